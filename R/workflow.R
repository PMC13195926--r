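#' Workflow configuration
#'
#' Bundles every tunable of the targeting workflow so a single object (and
#' its [settings_hash()]) fully determines the outputs.
#'
#' @param algorithms subset of `"tree"`, `"cluster"`, `"cone"`.
#' @param grid_spec a [threshold_grid()] (tree algorithm; also carries the
#'   FC direction used by all algorithms).
#' @param cluster_fc_percent cluster retention threshold in (0,100], or
#'   `"loocv"` to select it per subject by leave-one-out cross-validation.
#' @param kernel a [cone_kernel()].
#' @param model an [intensity_model()].
#' @param seed_radius_mm evaluation seed-region radius, mm.
#' @param cone_spacing_mm surface-seed spacing for the cone algorithm, mm.
#' @param connectivity component neighborhood (6/18/26).
#' @return A `run_config`.
#' @export
run_config <- function(algorithms = c("tree", "cluster", "cone"),
                       grid_spec = threshold_grid(),
                       cluster_fc_percent = 10,
                       kernel = cone_kernel(),
                       model = intensity_model(),
                       seed_radius_mm = 5,
                       cone_spacing_mm = 4,
                       connectivity = 26L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (!length(algorithms)) stop("no algorithms enabled")
  structure(list(algorithms = algorithms, grid_spec = grid_spec,
                 cluster_fc_percent = cluster_fc_percent, kernel = kernel,
                 model = model, seed_radius_mm = seed_radius_mm,
                 cone_spacing_mm = cone_spacing_mm,
                 connectivity = as.integer(connectivity)),
            class = "run_config")
}

cluster_direction <- function(grid_spec) grid_spec$fc_direction

## depth value at (or nearest valid voxel to) a target
depth_at_target <- function(depth, target) {
  v <- depth$value[matrix(target$voxel_index, nrow = 1)]
  if (!is.na(v)) return(v)
  idx <- which(depth$valid$member)
  w <- lin_to_world(depth$grid, idx)
  d2 <- colSums((t(w) - target$world_mm)^2)
  depth$value[idx[which.min(d2)]]
}

derive_targets_one_session <- function(subj, session, config,
                                       cluster_percent) {
  ts <- subj$sessions[[session]]
  seed <- subj$seed_timecourses[[session]]
  fc <- fc_map(ts, seed, subj$gray)
  dir <- cluster_direction(config$grid_spec)
  out <- list()
  if ("tree" %in% config$algorithms) {
    res <- tree_based_target(subj$parcellation, fc, subj$depth,
                             subj$anatomical_mask, subj$target_networks,
                             grid_spec = config$grid_spec,
                             connectivity = config$connectivity)
    out$tree <- res$target
  }
  if ("cluster" %in% config$algorithms) {
    roi <- mask_intersect(subj$anatomical_mask, subj$gray)
    out$cluster <- cluster_target(fc, roi, cluster_percent,
                                  direction = dir,
                                  connectivity = config$connectivity)
  }
  if ("cone" %in% config$algorithms) {
    brain <- if (!is.null(subj$brain)) subj$brain else subj$gray
    seeds <- surface_seeds(subj$anatomical_mask, brain,
                           spacing_mm = config$cone_spacing_mm)
    out$cone <- cone_target(fc, seeds, kernel = config$kernel,
                            direction = dir)
  }
  out
}

#' Run the full targeting and evaluation workflow on a cohort
#'
#' For every subject, targets are derived independently from each of the two
#' sessions by every enabled algorithm; the evaluation metrics are then
#' computed with the session-swap-and-average contract: the target from one
#' session is evaluated (depth, seed FC) against the other session's data,
#' the roles are reversed, and the two values averaged. Reliability uses the
#' Euclidean distance between a subject's two session targets (intra) and
#' the mean distance to other subjects' session-1 targets (inter); the
#' hypothetical stimulation-intensity reduction of the tree target relative
#' to each baseline is derived from the depth difference through the linear
#' intensity model. Subjects whose derivation fails are quarantined with a
#' logged reason; the workflow continues.
#'
#' @param subjects list of subjects (e.g. from [make_cohort()]); each must
#'   carry `grid`, `gray`, `depth`, `parcellation`, `anatomical_mask`,
#'   `target_networks`, and two entries in `sessions` /
#'   `seed_timecourses`.
#' @param config a [run_config()].
#' @return List with `targets` (the [target_table()]), `metrics` (one row
#'   per subject x algorithm: depth_mm, intra_mm, inter_mm, ratio, seed_fc,
#'   intensity_reduction_vs_tree), `quarantined` (named character vector of
#'   failure reasons) and `settings_hash`.
#' @export
run_workflow <- function(subjects, config = run_config()) {
  if (!length(subjects)) stop("empty cohort")
  hash <- settings_hash(unclass(config))
  n <- length(subjects)

  cluster_percents <- rep(NA_real_, n)
  if ("cluster" %in% config$algorithms) {
    if (identical(config$cluster_fc_percent, "loocv")) {
      if (n < 2L) stop("LOOCV threshold selection needs >= 2 subjects")
      loo <- lapply(subjects, function(s) {
        list(fc_train = fc_map(s$sessions[[1]], s$seed_timecourses[[1]],
                               s$gray),
             ts_eval = s$sessions[[2]], seed_eval = s$seed_timecourses[[2]],
             mask = mask_intersect(s$anatomical_mask, s$gray))
      })
      cluster_percents <- loocv_cluster_threshold(
        loo, direction = cluster_direction(config$grid_spec),
        seed_radius_mm = config$seed_radius_mm,
        connectivity = config$connectivity)
    } else {
      cluster_percents <- rep(config$cluster_fc_percent, n)
    }
  }

  per_subject <- vector("list", n)
  quarantined <- character(0)
  for (i in seq_len(n)) {
    per_subject[[i]] <- tryCatch({
      lapply(1:2, function(s) {
        derive_targets_one_session(subjects[[i]], s, config,
                                   cluster_percents[i])
      })
    }, error = function(e) {
      message("subject ", i, " quarantined: ", conditionMessage(e))
      quarantined[as.character(i)] <<- conditionMessage(e)
      NULL
    })
  }

  ok <- which(!vapply(per_subject, is.null, logical(1)))
  target_rows <- list()
  metric_rows <- list()
  for (i in ok) {
    subj <- subjects[[i]]
    tgt <- per_subject[[i]]
    depth_tree <- NA_real_
    if ("tree" %in% config$algorithms) {
      depth_tree <- mean(c(depth_at_target(subj$depth, tgt[[1]]$tree),
                           depth_at_target(subj$depth, tgt[[2]]$tree)))
    }
    for (alg in config$algorithms) {
      t1 <- tgt[[1]][[alg]]
      t2 <- tgt[[2]][[alg]]
      target_rows[[length(target_rows) + 1L]] <-
        target_table(list(t1, t2), subject = i, session = 1:2,
                     algorithm = alg, settings_hash = hash)
      depth_mm <- mean(c(depth_at_target(subj$depth, t1),
                         depth_at_target(subj$depth, t2)))
      others <- lapply(setdiff(ok, i),
                       function(j) per_subject[[j]][[1]][[alg]])
      rel <- reliability_ratio(list(t1, t2), others)
      fc12 <- target_seed_fc(t1, radius_mm = config$seed_radius_mm,
                             ts = subj$sessions[[2]],
                             seed = subj$seed_timecourses[[2]])
      fc21 <- target_seed_fc(t2, radius_mm = config$seed_radius_mm,
                             ts = subj$sessions[[1]],
                             seed = subj$seed_timecourses[[1]])
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        subject = i, algorithm = alg, depth_mm = depth_mm,
        intra_mm = rel$intra_mm, inter_mm = rel$inter_mm,
        ratio = rel$ratio, degenerate = rel$degenerate,
        seed_fc = mean(c(fc12, fc21)),
        intensity_reduction_vs_tree =
          if (alg == "tree" || is.na(depth_tree)) NA_real_
          else intensity_reduction(depth_mm, depth_tree, config$model),
        cluster_fc_percent = if (alg == "cluster") cluster_percents[i]
          else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(target_rows)) stop("every subject was quarantined")
  list(targets = do.call(rbind, target_rows),
       metrics = do.call(rbind, metric_rows),
       quarantined = quarantined, settings_hash = hash)
}
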