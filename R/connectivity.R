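#' Group-level seed weight map
#'
#' Wraps a group-level seed FC weight map (e.g. the subgenual-cingulate
#' weight map, or an anxiosomatic circuit map) together with an exclusion
#' mask of voxels barred from the weighted average (typically the
#' stimulation-site mask itself, so the seed time course is not contaminated
#' by the region being targeted). Weights may be negative.
#'
#' @param map a [scalar_map()] of weights.
#' @param exclusion optional [brain_mask()] of excluded voxels.
#' @return A `weight_map`.
#' @export
weight_map <- function(map, exclusion = NULL) {
  if (is.null(exclusion)) {
    exclusion <- brain_mask(map$grid, logical(n_voxels(map$grid)))
  }
  stopifnot_same_grid(map$grid, exclusion$grid)
  structure(list(map = map, exclusion = exclusion), class = "weight_map")
}

#' Weighted seed time course
#'
#' Computes the seed region's time course as a weighted average of voxel time
#' courses, with weights from a group-level seed FC map. Only gray-matter
#' voxels outside the exclusion mask contribute. The default contract is the
#' normalized weighted mean sum(w_i x_i(t)) / sum(w_i); `mode = "abs"`
#' divides by sum(|w_i|) instead, which keeps the scale stable when positive
#' and negative weights nearly cancel.
#'
#' @param ts a [timeseries_volume()].
#' @param w a [weight_map()].
#' @param gray gray-matter [brain_mask()].
#' @param mode `"normalized"` (divide by sum of weights, default) or `"abs"`
#'   (divide by sum of absolute weights).
#' @return A `seed_timecourse`: list with `values` (length T) and
#'   `provenance`.
#' @export
weighted_seed_timecourse <- function(ts, w, gray,
                                     mode = c("normalized", "abs")) {
  mode <- match.arg(mode)
  stopifnot_same_grid(ts$grid, w$map$grid)
  stopifnot_same_grid(ts$grid, gray$grid)
  contrib <- gray$member & w$map$valid$member & !w$exclusion$member &
    ts$valid$member
  idx <- which(contrib)
  if (!length(idx)) stop("no contributing voxels (gray ∩ valid \\ exclusion empty)")
  wt <- w$map$value[idx]
  denom <- if (mode == "normalized") sum(wt) else sum(abs(wt))
  if (abs(denom) < 1e-12 * sum(abs(wt))) {
    stop("weights sum to ~0 under normalized mode; use mode = \"abs\"")
  }
  vals <- as.numeric(ts$series[, idx, drop = FALSE] %*% wt) / denom
  seed_timecourse(vals, provenance = list(mode = mode, n_voxels = length(idx)))
}

#' Seed time course
#'
#' @param values numeric vector, one value per frame.
#' @param provenance named list (weight-map id, run id, ...).
#' @return A `seed_timecourse`.
#' @export
seed_timecourse <- function(values, provenance = list()) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("seed time course must be finite")
  structure(list(values = values, provenance = provenance,
                 zero_variance = stats::sd(values) == 0),
            class = "seed_timecourse")
}

#' @export
print.seed_timecourse <- function(x, ...) {
  cat("seed_timecourse:", length(x$values), "frames",
      if (x$zero_variance) "(zero variance!)" else "", "\n")
  invisible(x)
}

## Pearson r of y against each column of X; zero-variance columns -> NA.
pearson_vec <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  Xc <- sweep(X, 2, colMeans(X))
  sx <- sqrt(colSums(Xc^2))
  r <- as.numeric(crossprod(Xc, yc)) / (sx * sy)
  r[sx == 0] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' Voxelwise seed functional-connectivity map
#'
#' Pearson correlation between the seed time course and every ROI voxel's
#' time course. Zero-variance voxels are undefined (excluded from the result
#' validity mask), never silently zero.
#'
#' @param ts a [timeseries_volume()] with at least 3 frames.
#' @param seed a [seed_timecourse()] with nonzero variance.
#' @param roi [brain_mask()] restricting where FC is computed.
#' @return A [scalar_map()] of correlations in \[-1, 1\].
#' @export
fc_map <- function(ts, seed, roi) {
  stopifnot_same_grid(ts$grid, roi$grid)
  if (length(seed$values) != ts$n_frames) {
    stop("seed length does not match number of frames")
  }
  if (seed$zero_variance) stop("seed time course has zero variance")
  idx <- which(roi$member & ts$valid$member)
  val <- rep(NA_real_, n_voxels(ts$grid))
  if (length(idx)) {
    val[idx] <- pearson_vec(ts$series[, idx, drop = FALSE], seed$values)
  }
  scalar_map(ts$grid, val)
}

#' Inter-session seed FC at a target
#'
#' Evaluation metric: the target from one session is used as a spherical seed
#' region in another session's data, and its mean time course is correlated
#' with that session's weighted seed time course. A more negative value
#' indicates stronger anticorrelation with the deep seed (better for
#' depression targeting).
#'
#' @param target a [target_point()].
#' @param radius_mm radius of the spherical target region, mm (default 5).
#' @param ts a [timeseries_volume()] from the evaluation session.
#' @param seed a [seed_timecourse()] from the same session.
#' @return Pearson correlation (single number).
#' @export
target_seed_fc <- function(target, radius_mm = 5, ts, seed) {
  region <- sphere_mask(ts$grid, target$world_mm, radius_mm)
  idx <- which(region$member & ts$valid$member)
  if (!length(idx)) stop("target region contains no valid voxels")
  m <- rowMeans(ts$series[, idx, drop = FALSE])
  r <- pearson_vec(matrix(m, ncol = 1), seed$values)
  if (is.na(r)) stop("target region mean series has zero variance")
  r
}
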