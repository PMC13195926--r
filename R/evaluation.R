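#' Linear distance-to-intensity model
#'
#' Converts a change in target distance-to-scalp into a change in TMS
#' stimulation intensity. The model is linear: a 1-mm reduction in
#' distance-to-scalp corresponds to a 3% decrease in intensity at 100% of the
#' resting motor threshold (RMT), scaled by the dosage expressed as a
#' fraction of RMT — e.g. 2.7% per mm at 90% RMT.
#'
#' @param pct_per_mm_at_100rmt slope at full RMT, percent per mm (default 3).
#' @param rmt_fraction dosage as a fraction of RMT, in (0, 1].
#' @return An `intensity_model`.
#' @export
intensity_model <- function(pct_per_mm_at_100rmt = 3.0, rmt_fraction = 0.9) {
  if (rmt_fraction <= 0 || rmt_fraction > 1) {
    stop("'rmt_fraction' must be in (0, 1]")
  }
  structure(list(pct_per_mm_at_100rmt = pct_per_mm_at_100rmt,
                 rmt_fraction = rmt_fraction,
                 slope = pct_per_mm_at_100rmt * rmt_fraction),
            class = "intensity_model")
}

#' Stimulation-intensity reduction from a distance change
#'
#' `(d_ref - d_new) * slope`, where the slope is the 100%-RMT percent-per-mm
#' rate scaled by the RMT fraction. Positive values mean the new target can
#' be stimulated at lower intensity (it is closer to the scalp); the function
#' is linear and antisymmetric in its two distance arguments.
#'
#' @param d_ref_mm reference target's distance-to-scalp, mm.
#' @param d_new_mm new target's distance-to-scalp, mm.
#' @param model an [intensity_model()].
#' @return Intensity reduction in percent.
#' @examples
#' intensity_reduction(1, 0, intensity_model(rmt_fraction = 0.9))  # 2.7
#' @export
intensity_reduction <- function(d_ref_mm, d_new_mm,
                                model = intensity_model()) {
  if (any(d_ref_mm < 0) || any(d_new_mm < 0)) {
    stop("distances must be non-negative")
  }
  (d_ref_mm - d_new_mm) * model$slope
}

#' Inter-/intra-individual distance reliability
#'
#' Test-retest reliability of a targeting algorithm. The intra-individual
#' distance is the Euclidean distance between a subject's targets from two
#' sessions; the inter-individual distance is the mean distance between the
#' subject's session-1 target and the other individuals' targets (already
#' transformed into the subject's frame by the caller). The ratio
#' inter/intra is larger for more reliable targeting. When the two session
#' targets coincide (intra = 0, e.g. a group-level target) the ratio is
#' undefined and flagged infinite rather than treated as a large value;
#' flagged subjects should be excluded from group summaries.
#'
#' @param own_pair list of two [target_point()]s (session 1, session 2).
#' @param others list of other individuals' [target_point()]s (session-1
#'   targets by default; may be empty, flagging `inter` undefined).
#' @return List with `intra_mm`, `inter_mm`, `ratio`, and `degenerate`
#'   (TRUE when intra = 0 or `others` is empty).
#' @export
reliability_ratio <- function(own_pair, others) {
  if (length(own_pair) != 2L) stop("'own_pair' must hold exactly 2 targets")
  intra <- target_distance(own_pair[[1]], own_pair[[2]])
  if (length(others)) {
    inter <- mean(vapply(others,
                         function(o) target_distance(own_pair[[1]], o),
                         numeric(1)))
  } else {
    inter <- NA_real_
  }
  degenerate <- intra == 0 || is.na(inter)
  ratio <- if (is.na(inter)) NA_real_ else if (intra == 0) Inf else inter / intra
  list(intra_mm = intra, inter_mm = inter, ratio = ratio,
       degenerate = degenerate)
}

#' E-field map
#'
#' A simulated electric-field magnitude map, either on a voxel grid (a
#' [scalar_map()]) or as a list of locations with values (surface vertices).
#' Magnitudes must be non-negative. Simulation itself is external; maps are
#' inputs.
#'
#' @param values [scalar_map()] or numeric vector of magnitudes.
#' @param coords n x 3 matrix of world coordinates, required when `values`
#'   is a vector.
#' @param provenance named list (target id, run id).
#' @return An `efield_map` with `values` (numeric vector), `coords`,
#'   and optionally `grid`/`valid` when grid-based.
#' @export
efield_map <- function(values, coords = NULL, provenance = list()) {
  if (inherits(values, "scalar_map")) {
    idx <- which(values$valid$member)
    v <- values$value[idx]
    out <- list(values = v, coords = lin_to_world(values$grid, idx),
                idx = idx, grid = values$grid, provenance = provenance)
  } else {
    v <- as.numeric(values)
    coords <- rbind3(coords)
    if (is.null(coords) || nrow(coords) != length(v)) {
      stop("'coords' must supply one location per value")
    }
    out <- list(values = v, coords = coords, idx = seq_along(v),
                grid = NULL, provenance = provenance)
  }
  if (any(out$values < 0, na.rm = TRUE)) stop("E-field magnitudes must be non-negative")
  structure(out, class = "efield_map")
}

#' E-field hotspot
#'
#' The locations carrying the top `top_percent`% of E-field magnitude
#' (nearest-rank, deterministic tie-break by location index). Typical values
#' are 0.1% to 1%.
#'
#' @param e an [efield_map()].
#' @param top_percent in (0, 100].
#' @return Integer vector of hotspot location indices (positions within
#'   `e$values`).
#' @export
efield_hotspot <- function(e, top_percent) {
  if (top_percent <= 0 || top_percent > 100) {
    stop("'top_percent' must be in (0, 100]")
  }
  n <- length(e$values)
  if (!n) stop("empty E-field map")
  k <- as.integer(ceiling(top_percent / 100 * n))
  ord <- order(-e$values, seq_len(n))
  sort(ord[seq_len(k)])
}

#' Network specificity of an E-field hotspot
#'
#' The percentage of the hotspot area occupied by the target networks of an
#' unseen run: sum of area over hotspot locations labeled with a target
#' network, divided by total hotspot area, times 100. Areas default to
#' uniform (a voxel count) when `area_weights` is absent.
#'
#' @param hotspot integer location indices from [efield_hotspot()].
#' @param labels integer network label per location of the E-field map
#'   (for grid-based maps, the parcellation sampled at `e$idx`).
#' @param target_networks integer set of target network labels.
#' @param area_weights optional per-location areas.
#' @return Percentage in \[0, 100\].
#' @export
network_specificity <- function(hotspot, labels, target_networks,
                                area_weights = NULL) {
  if (!length(hotspot)) stop("empty hotspot")
  if (is.null(area_weights)) area_weights <- rep(1, length(labels))
  a <- area_weights[hotspot]
  inn <- labels[hotspot] %in% as.integer(target_networks)
  100 * sum(a[inn]) / sum(a)
}

#' Hotspot seed FC
#'
#' Correlation between the E-field-weighted mean time course of the hotspot
#' locations and the seed time course, all from the unseen run. Weights are
#' the local E-field magnitudes, so the result is invariant to a global
#' rescaling of the E-field map.
#'
#' @param hotspot integer location indices from [efield_hotspot()].
#' @param e the [efield_map()] (grid-based, so locations map to voxels).
#' @param ts a [timeseries_volume()] on the same grid.
#' @param seed a [seed_timecourse()].
#' @return Pearson correlation.
#' @export
hotspot_seed_fc <- function(hotspot, e, ts, seed) {
  if (is.null(e$grid)) stop("hotspot_seed_fc needs a grid-based E-field map")
  stopifnot_same_grid(e$grid, ts$grid)
  vox <- e$idx[hotspot]
  ok <- ts$valid$member[vox]
  if (!any(ok)) stop("hotspot does not overlap valid time-series voxels")
  w <- e$values[hotspot][ok]
  x <- as.numeric(ts$series[, vox[ok], drop = FALSE] %*% w) / sum(w)
  r <- pearson_vec(matrix(x, ncol = 1), seed$values)
  if (is.na(r)) stop("weighted hotspot series has zero variance")
  r
}

#' E-field reliability ratio
#'
#' Intra-individual correlation is the Pearson correlation between a
#' subject's two run E-field maps; inter-individual correlation is the mean
#' correlation between the run-1 map and other individuals' maps (all in the
#' subject's frame). The reported ratio is inter/intra. Note the favorable
#' direction is *smaller* here — high within-subject reproducibility with
#' low between-subject similarity — which is opposite to the distance-based
#' reliability ratio; the output records this explicitly.
#'
#' @param e_run1,e_run2 the subject's two [efield_map()]s (same locations).
#' @param e_others list of other individuals' [efield_map()]s.
#' @return List with `intra_r`, `inter_r`, `ratio`, and
#'   `favorable_direction = "smaller"`.
#' @export
efield_reliability <- function(e_run1, e_run2, e_others) {
  corr <- function(a, b) {
    if (length(a$values) != length(b$values)) {
      stop("E-field maps have different numbers of locations")
    }
    if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0) {
      stop("zero-variance E-field map")
    }
    stats::cor(a$values, b$values)
  }
  intra <- corr(e_run1, e_run2)
  inter <- if (length(e_others)) {
    mean(vapply(e_others, function(o) corr(e_run1, o), numeric(1)))
  } else NA_real_
  list(intra_r = intra, inter_r = inter, ratio = inter / intra,
       favorable_direction = "smaller")
}
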