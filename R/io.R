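#' Read a NIfTI volume as a typed container
#'
#' Loads a NIfTI-1 file and wraps it in the container matching its expected
#' role. The grid affine is taken verbatim from the header. Label volumes
#' must be exactly integer-valued (1.0 and 2.0 stored as floats are
#' accepted; 1.5 is rejected).
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param expected one of `"scalar"`, `"label"`, `"mask"`, `"timeseries"`.
#' @param reference_grid optional [volume_grid()]; a shape mismatch is an
#'   error naming both shapes.
#' @return A [scalar_map()], [label_map()], [brain_mask()] or
#'   [timeseries_volume()].
#' @export
load_volume <- function(path,
                        expected = c("scalar", "label", "mask", "timeseries"),
                        reference_grid = NULL) {
  expected <- match.arg(expected)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  dims <- dim(img)
  if (expected == "timeseries") {
    if (length(dims) != 4L) stop("expected a 4D time-series volume: ", path)
    shape <- dims[1:3]
  } else {
    if (length(dims) == 4L && dims[4] == 1L) {
      img <- img[, , , 1]
      dims <- dim(img)
    }
    if (length(dims) != 3L) stop("expected a 3D volume: ", path)
    shape <- dims
  }
  grid <- volume_grid(shape, matrix(as.numeric(aff), 4, 4))
  if (!is.null(reference_grid) && !identical(reference_grid$shape, grid$shape)) {
    stop("shape mismatch: file is ", paste(grid$shape, collapse = "x"),
         ", reference grid is ", paste(reference_grid$shape, collapse = "x"))
  }
  vals <- as.array(img)
  switch(expected,
         scalar = scalar_map(grid, vals),
         label = label_map(grid, vals),
         mask = brain_mask(grid, vals != 0),
         timeseries = timeseries_volume(grid, vals))
}

#' Write a typed container as NIfTI
#'
#' Masks are written as uint8, label maps as int32, scalar maps (with
#' undefined voxels as NaN) and time series as float.
#'
#' @param x a [scalar_map()], [label_map()], [brain_mask()] or
#'   [timeseries_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(x, path) {
  grid <- x$grid
  if (inherits(x, "brain_mask")) {
    arr <- array(as.integer(x$member), grid$shape)
    dt <- "uint8"
  } else if (inherits(x, "label_map")) {
    arr <- x$label
    dt <- "int32"
  } else if (inherits(x, "scalar_map")) {
    arr <- x$value
    dt <- "double"
  } else if (inherits(x, "timeseries_volume")) {
    arr <- array(t(x$series), c(grid$shape, x$n_frames))
    dt <- "double"
  } else {
    stop("unsupported object of class ", paste(class(x), collapse = "/"))
  }
  img <- RNifti::asNifti(arr, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Target table
#'
#' Assembles [target_point()]s into the shared tabular schema used by all
#' CLI subcommands: one row per subject x session x algorithm with world
#' coordinates and a settings hash for provenance.
#'
#' @param targets list of [target_point()]s.
#' @param subject,session,algorithm vectors recycled against `targets`.
#' @param settings_hash provenance hash string (see [settings_hash()]).
#' @return data.frame with columns subject, session, algorithm, x_mm, y_mm,
#'   z_mm, n_candidates, settings_hash.
#' @export
target_table <- function(targets, subject, session, algorithm,
                         settings_hash = "") {
  n <- length(targets)
  xyz <- t(vapply(targets, function(t) t$world_mm, numeric(3)))
  stopifnot(all(is.finite(xyz)))
  data.frame(
    subject = rep_len(subject, n), session = rep_len(session, n),
    algorithm = rep_len(algorithm, n),
    x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
    n_candidates = vapply(targets, function(t) {
      if (is.null(t$meta$n_candidates)) NA_integer_
      else as.integer(t$meta$n_candidates)
    }, integer(1)),
    settings_hash = rep_len(settings_hash, n),
    stringsAsFactors = FALSE)
}

#' Deterministic hash of a settings object
#'
#' MD5 of the canonical deparse of the object; identical settings always
#' produce the identical hash, so every output row is traceable to the exact
#' configuration that produced it.
#'
#' @param x any R object (e.g. a [run_config()]).
#' @return 32-character hex string.
#' @export
settings_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

#' Write a table with its JSON provenance sidecar
#'
#' Tables go out as TSV; a `.json` sidecar records the configuration and
#' package version so outputs remain diff-able and traceable.
#'
#' @param df data.frame.
#' @param path output `.tsv` path.
#' @param config optional configuration list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, config = NULL) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  meta <- list(
    package = "treetarget",
    version = as.character(utils::packageVersion("treetarget")),
    n_rows = nrow(df), config = config)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Export a candidate forest as JSON for audit
#'
#' @param forest a [build_forest()] result.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(forest, path) {
  trees <- lapply(forest$trees, function(nodes) {
    lapply(nodes, function(nd) {
      list(id = nd$id, fc_percent = nd$fc_percent,
           depth_percent = nd$depth_percent,
           centroid_mm = nd$centroid, n_voxels = length(nd$voxels),
           children = nd$children,
           parent = if (is.na(nd$parent)) NULL else nd$parent)
    })
  })
  jsonlite::write_json(
    list(trees = trees, candidates = forest$candidate_info,
         settings = list(
           depth_percents = forest$settings$grid_spec$depth_percents,
           fc_percents = forest$settings$grid_spec$fc_percents,
           fc_direction = forest$settings$grid_spec$fc_direction,
           connectivity = forest$settings$connectivity,
           dedup_tol_mm = forest$settings$dedup_tol_mm)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
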