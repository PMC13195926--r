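#' Specification of a synthetic phantom head
#'
#' The phantom emulates exactly the statistical structure the targeting
#' algorithms consume: a spherical head, a cortical shell whose outer surface
#' undulates sinusoidally (producing shallow "gyral" and deep "sulcal" gray
#' voxels with an analytically known distance-to-scalp), an angular-sector
#' network parcellation, a unit-variance seed signal, and voxel time courses
#' coupled to that signal through signed Gaussian blobs planted at known
#' locations. It makes no attempt at BOLD physics, motion or physiological
#' noise.
#'
#' Blobs are specified by direction (azimuth/elevation, radians), a radial
#' `position` (`"shallow"`: just under the outer cortical surface; `"deep"`:
#' just above the inner surface), a coupling `amplitude` (signed; negative =
#' anticorrelated with the seed) and a spatial `sigma_mm`. The noiseless
#' voxel-seed correlation at a blob center is sign(a), and with white noise
#' of standard deviation s it attenuates to a / sqrt(a^2 + s^2).
#'
#' @param shape grid shape (default 40^3).
#' @param voxel_mm isotropic voxel size, mm (default 3).
#' @param head_radius_mm scalp sphere radius (default 52).
#' @param scalp_offset_mm gap between scalp and outer cortex (default 6).
#' @param shell_thickness_mm cortical shell thickness (default 9).
#' @param fold_amplitude_mm amplitude of the sinusoidal folds (default 3);
#'   the analytic depth then spans about `shell_thickness + 2 * amplitude`.
#' @param fold_frequency angular frequency of the folds (default 5).
#' @param n_networks number of azimuthal network sectors (default 4).
#' @param target_networks labels treated as stimulation-target networks.
#' @param blobs data.frame with columns `az`, `el`, `position`, `amplitude`,
#'   `sigma_mm`; default is a single shallow anticorrelated blob
#'   (amplitude -0.8, sigma 6 mm) centered in the target-network sectors.
#' @param mask_radius_mm radius of the anatomical (DLPFC-like) sphere mask
#'   around the nominal first-blob scalp point (default 32).
#' @param noise_sigma per-voxel noise standard deviation added to every gray
#'   voxel's series (default 0.5).
#' @param bg_fc_sd standard deviation of the smooth per-subject background
#'   coupling field added to the planted blobs (default 0.15). Real seed-FC
#'   maps are graded everywhere, not flat outside the target region; without
#'   this term the threshold sweep would order functionally indifferent
#'   voxels by pure noise. Set 0 to disable.
#' @param bg_fc_fwhm_mm spatial smoothness (FWHM) of the background coupling
#'   field, mm (default 15).
#' @param smooth_fwhm_mm spatial full-width-half-maximum of the Gaussian
#'   smoothing applied to the noise field (default 4, matching the volumetric
#'   smoothing such data receive in preprocessing; 0 disables it). The noise
#'   is renormalized after smoothing so its per-voxel standard deviation
#'   remains `noise_sigma`, keeping the FC attenuation law exact.
#' @param n_frames frames per session (default 100).
#' @param network_jitter_sd_rad per-subject rotation jitter of the sector
#'   parcellation, radians (default 0.09, about 5 degrees).
#' @param blob_jitter_sd_mm per-subject translation jitter of blob centers
#'   (default 1).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40L, 40L, 40L), voxel_mm = 3,
                         head_radius_mm = 52, scalp_offset_mm = 6,
                         shell_thickness_mm = 9, fold_amplitude_mm = 3,
                         fold_frequency = 5, n_networks = 4L,
                         target_networks = c(1L, 2L),
                         blobs = NULL, mask_radius_mm = 32,
                         noise_sigma = 0.5, smooth_fwhm_mm = 4,
                         bg_fc_sd = 0.15, bg_fc_fwhm_mm = 15,
                         n_frames = 100L,
                         network_jitter_sd_rad = 0.09,
                         blob_jitter_sd_mm = 1) {
  if (shell_thickness_mm < voxel_mm) {
    stop("cortical shell thinner than one voxel")
  }
  if (scalp_offset_mm + shell_thickness_mm + fold_amplitude_mm >=
      head_radius_mm) {
    stop("cortex shell does not fit inside the head")
  }
  if (is.null(blobs)) {
    ## default: one anticorrelated blob on a gyral crest (fold field = +1 at
    ## az = -3*pi/10, el = pi/2 for the default frequency 5), well inside the
    ## target-network sectors, so its voxels are genuinely near-scalp
    blobs <- data.frame(az = -3 * pi / 10, el = pi / 2,
                        position = "shallow",
                        amplitude = -0.8, sigma_mm = 6,
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("az", "el", "position", "amplitude", "sigma_mm") %in%
                  names(blobs)),
            all(blobs$position %in% c("shallow", "deep")))
  structure(list(
    shape = as.integer(shape), voxel_mm = voxel_mm,
    head_radius_mm = head_radius_mm, scalp_offset_mm = scalp_offset_mm,
    shell_thickness_mm = shell_thickness_mm,
    fold_amplitude_mm = fold_amplitude_mm, fold_frequency = fold_frequency,
    n_networks = as.integer(n_networks),
    target_networks = as.integer(target_networks),
    blobs = blobs, mask_radius_mm = mask_radius_mm,
    noise_sigma = noise_sigma, smooth_fwhm_mm = smooth_fwhm_mm,
    bg_fc_sd = bg_fc_sd, bg_fc_fwhm_mm = bg_fc_fwhm_mm,
    n_frames = as.integer(n_frames),
    network_jitter_sd_rad = network_jitter_sd_rad,
    blob_jitter_sd_mm = blob_jitter_sd_mm
  ), class = "phantom_spec")
}

#' Unambiguous-recovery phantom specification
#'
#' The configuration used for planted-target recovery experiments: a single
#' wide anticorrelated cluster (sigma 15 mm) dominating the FC ordering over
#' the whole stimulation mask, low noise (sigma 0.1), no background coupling
#' field, and slightly deeper folds (amplitude 4 mm) so the near-scalp strip
#' is well defined against voxel discretization. A consensus (medoid)
#' algorithm can only be expected to localize a planted target to within a
#' voxel when the anticorrelation structure over the search region is
#' unimodal like this; the [phantom_spec()] defaults instead emulate the
#' harder, more realistic regime with background structure and higher noise.
#'
#' @param ... overrides passed to [phantom_spec()].
#' @export
phantom_spec_recovery <- function(...) {
  blobs <- data.frame(az = -3 * pi / 10, el = pi / 2, position = "shallow",
                      amplitude = -0.8, sigma_mm = 15,
                      stringsAsFactors = FALSE)
  phantom_spec(blobs = blobs, noise_sigma = 0.1, bg_fc_sd = 0,
               fold_amplitude_mm = 4, ...)
}

#' Two-blob phantom specification
#'
#' Convenience variant with a strong deep blob and a weaker shallow blob,
#' angularly separated, used to contrast depth-aware and depth-blind
#' targeting: a depth-blind algorithm chases the stronger deep blob while a
#' near-scalp algorithm settles on the gyral one.
#'
#' @param ... passed to [phantom_spec()].
#' @export
phantom_spec_two_blob <- function(...) {
  ## shallow weaker blob on a gyral crest, strong deep blob in a sulcal
  ## trough ~27 mm away (both inside the target-network sectors)
  blobs <- data.frame(
    az = c(-3 * pi / 10, -pi / 2), el = c(pi / 2, pi / 2),
    position = c("shallow", "deep"), amplitude = c(-0.55, -0.9),
    sigma_mm = c(5, 6), stringsAsFactors = FALSE)
  phantom_spec(blobs = blobs, ...)
}

phantom_grid <- function(spec) {
  aff <- diag(c(rep(spec$voxel_mm, 3), 1))
  ## center the head at world (0,0,0)
  aff[1:3, 4] <- -spec$voxel_mm * (spec$shape - 1) / 2
  volume_grid(spec$shape, aff)
}

## frequency-domain separable Gaussian kernel (circular convolution); the
## wrap-around is negligible because the head leaves a margin at the grid
## edge much wider than the kernel support
gaussian_kernel_fft <- function(shape, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  k1 <- lapply(1:3, function(a) {
    n <- shape[a]
    x <- c(0:(n %/% 2), seq_len(n - n %/% 2 - 1) - (n - n %/% 2))
    w <- exp(-x^2 / (2 * sigma_vox[a]^2))
    w / sum(w)
  })
  k <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  list(K = stats::fft(k), l2 = sqrt(sum(k^2)))
}

unit_dir <- function(az, el) {
  c(cos(az) * sin(el), sin(az) * sin(el), cos(el))
}

## fold field on the unit sphere, in [-1, 1]: gyral ridges running along
## meridians (crowns are extended 1D structures, as on real cortex), with a
## gentle height modulation along each ridge so crowns are broad bumps
## rather than knife edges
fold_field <- function(spec, az, el) {
  sin(spec$fold_frequency * az) * (0.7 + 0.3 * sin(spec$fold_frequency * el))
}

## nominal (un-jittered) blob centers in world mm
blob_centers <- function(spec) {
  t(vapply(seq_len(nrow(spec$blobs)), function(i) {
    b <- spec$blobs[i, ]
    f <- fold_field(spec, b$az, b$el)
    r_outer <- spec$head_radius_mm - spec$scalp_offset_mm +
      spec$fold_amplitude_mm * f
    r <- if (b$position == "shallow") r_outer - 1.5 else
      r_outer - spec$shell_thickness_mm + 1.5
    r * unit_dir(b$az, b$el)
  }, numeric(3)))
}

#' Synthetic head geometry
#'
#' Builds the spherical head mask, the folded cortical-shell gray-matter
#' mask, and the analytic distance-to-scalp map (head radius minus voxel
#' radius — exact for a spherical scalp). Purely deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return List with `grid`, `head`, `gray` and `depth` (a [scalar_map()]
#'   valid on gray).
#' @export
make_head <- function(spec) {
  grid <- phantom_grid(spec)
  w <- lin_to_world(grid, seq_len(n_voxels(grid)))
  r <- sqrt(rowSums(w^2))
  az <- atan2(w[, 2], w[, 1])
  el <- acos(pmin(pmax(ifelse(r > 0, w[, 3] / r, 1), -1), 1))
  head <- r <= spec$head_radius_mm
  f <- fold_field(spec, az, el)
  r_outer <- spec$head_radius_mm - spec$scalp_offset_mm +
    spec$fold_amplitude_mm * f
  gray <- r <= r_outer & r >= r_outer - spec$shell_thickness_mm
  depth <- rep(NA_real_, length(r))
  depth[gray] <- spec$head_radius_mm - r[gray]
  head_m <- brain_mask(grid, head)
  gray_m <- brain_mask(grid, gray)
  ## solid brain (everything under the cortical surface): its exterior
  ## boundary is the outer brain surface, as for a real brain mask
  brain_m <- brain_mask(grid, r <= r_outer)
  list(grid = grid, head = head_m, gray = gray_m, brain = brain_m,
       depth = scalar_map(grid, depth, valid = gray_m))
}

## sector parcellation of the gray shell, rotated by delta_az
phantom_parcellation <- function(spec, geom, delta_az = 0) {
  grid <- geom$grid
  w <- lin_to_world(grid, seq_len(n_voxels(grid)))
  az <- atan2(w[, 2], w[, 1]) - delta_az
  az <- ((az + pi) %% (2 * pi))              # wrap to [0, 2*pi)
  lab <- 1L + as.integer(floor(az / (2 * pi) * spec$n_networks))
  lab[lab > spec$n_networks] <- spec$n_networks
  lab[!geom$gray$member] <- 0L
  label_map(grid, lab)
}

#' Synthetic phantom subject
#'
#' Generates one subject: the shared head geometry, a subject-jittered
#' parcellation and blob layout (between-subject variability as rigid jitter
#' plus amplitude scaling, shared across that subject's sessions), and one
#' time-series volume plus generating seed time course per session seed
#' (within-subject variability is noise only). All randomness derives from
#' the supplied seeds, so generation is fully reproducible.
#'
#' @param spec a [phantom_spec()].
#' @param subject_seed integer seed for between-subject jitter.
#' @param session_seeds integer vector, one seed per session.
#' @return A `phantom_subject`: list with `grid`, `head`, `gray`, `brain`
#'   (solid brain mask whose exterior boundary is the outer brain surface),
#'   `depth`,
#'   `parcellation`, `anatomical_mask`, `target_networks`, `sessions` (list
#'   of [timeseries_volume()]), `seed_timecourses` (list of
#'   [seed_timecourse()]), `truth` (matrix of jittered blob centers, mm) and
#'   `coupling` (the subject's coupling [scalar_map()]).
#' @export
make_subject <- function(spec, subject_seed, session_seeds) {
  if (!length(session_seeds)) stop("at least one session seed is required")
  geom <- make_head(spec)
  grid <- geom$grid

  set.seed(as.integer(subject_seed) %% .Machine$integer.max)
  delta_az <- stats::rnorm(1, 0, spec$network_jitter_sd_rad)
  n_blob <- nrow(spec$blobs)
  jitter <- matrix(stats::rnorm(3 * n_blob, 0, spec$blob_jitter_sd_mm),
                   ncol = 3)
  amp_scale <- 1 + stats::rnorm(n_blob, 0, 0.05)

  parc <- phantom_parcellation(spec, geom, delta_az)
  centers <- blob_centers(spec) + jitter
  amps <- spec$blobs$amplitude * amp_scale

  gidx <- mask_indices(geom$gray)
  gw <- lin_to_world(grid, gidx)
  coupling_g <- numeric(length(gidx))
  for (i in seq_len(n_blob)) {
    d2 <- colSums((t(gw) - centers[i, ])^2)
    coupling_g <- coupling_g + amps[i] * exp(-d2 / (2 * spec$blobs$sigma_mm[i]^2))
  }
  if (spec$bg_fc_sd > 0) {
    ## smooth per-subject background coupling: seed-FC maps are graded
    ## everywhere, never flat outside the planted region
    bgk <- gaussian_kernel_fft(spec$shape,
                               (spec$bg_fc_fwhm_mm / 2.3548) / spec$voxel_mm)
    wfield <- array(stats::rnorm(n_voxels(grid)), spec$shape)
    bg <- Re(stats::fft(stats::fft(wfield) * bgk$K, inverse = TRUE)) /
      n_voxels(grid)
    coupling_g <- coupling_g + spec$bg_fc_sd * bg[gidx] / bgk$l2
  }
  coupling <- rep(NA_real_, n_voxels(grid))
  coupling[gidx] <- coupling_g

  nominal_center1 <- blob_centers(spec)[1, ]
  anat <- sphere_mask(grid, nominal_center1 / sqrt(sum(nominal_center1^2)) *
                        (spec$head_radius_mm - spec$scalp_offset_mm),
                      spec$mask_radius_mm)

  kern <- if (spec$smooth_fwhm_mm > 0) {
    gaussian_kernel_fft(spec$shape,
                        (spec$smooth_fwhm_mm / 2.3548) / spec$voxel_mm)
  } else NULL

  sessions <- list()
  seeds <- list()
  for (s in seq_along(session_seeds)) {
    set.seed(as.integer(session_seeds[s]) %% .Machine$integer.max)
    sig <- stats::rnorm(spec$n_frames)
    series <- matrix(0, nrow = spec$n_frames, ncol = n_voxels(grid))
    signal <- outer(sig, coupling_g)
    if (is.null(kern)) {
      noise <- matrix(stats::rnorm(spec$n_frames * length(gidx),
                                   0, spec$noise_sigma),
                      nrow = spec$n_frames)
    } else {
      ## spatially correlated noise: white field smoothed by FFT convolution,
      ## rescaled so the per-voxel sd is exactly noise_sigma
      noise <- matrix(0, nrow = spec$n_frames, ncol = length(gidx))
      nv <- n_voxels(grid)
      for (t in seq_len(spec$n_frames)) {
        w <- array(stats::rnorm(nv), spec$shape)
        sm <- Re(stats::fft(stats::fft(w) * kern$K, inverse = TRUE)) / nv
        noise[t, ] <- spec$noise_sigma * sm[gidx] / kern$l2
      }
    }
    series[, gidx] <- signal + noise
    sessions[[s]] <- timeseries_volume(grid, series, valid = geom$gray)
    seeds[[s]] <- seed_timecourse(sig, provenance = list(
      source = "phantom", session_seed = session_seeds[s]))
  }

  structure(list(
    grid = grid, head = geom$head, gray = geom$gray, brain = geom$brain,
    depth = geom$depth,
    parcellation = parc, anatomical_mask = anat,
    target_networks = spec$target_networks,
    sessions = sessions, seed_timecourses = seeds,
    truth = centers, coupling = scalar_map(grid, coupling, valid = geom$gray),
    spec = spec, subject_seed = subject_seed, session_seeds = session_seeds
  ), class = "phantom_subject")
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat("phantom_subject on", format(x$grid), "-", length(x$sessions),
      "sessions,", nrow(x$truth), "planted blobs\n")
  invisible(x)
}

#' Analytic distance-to-scalp of an arbitrary point
#'
#' For the spherical phantom head, the distance from any interior point to
#' the scalp is simply the head radius minus the point's distance from the
#' head center.
#'
#' @param spec a [phantom_spec()].
#' @param world_mm point (or n x 3 matrix of points) in world mm.
#' @return Distance(s) in mm.
#' @export
phantom_depth_at <- function(spec, world_mm) {
  w <- rbind3(world_mm)
  spec$head_radius_mm - sqrt(rowSums(w^2))
}

#' Reproducible phantom cohort
#'
#' Generates `n_subjects` phantom subjects with `n_sessions` sessions each.
#' All per-subject and per-session seeds are drawn deterministically from
#' `base_seed`, so the same call always yields a bit-identical cohort. All
#' subjects share one grid; cross-subject registration is the identity.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects (>= 1).
#' @param base_seed integer master seed.
#' @param n_sessions sessions per subject (default 2).
#' @return List of `phantom_subject`s.
#' @export
make_cohort <- function(spec, n_subjects, base_seed, n_sessions = 2L) {
  if (n_subjects < 1L) stop("need at least one subject")
  set.seed(as.integer(base_seed) %% .Machine$integer.max)
  all_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 n_subjects * (1L + n_sessions)),
                      nrow = n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    make_subject(spec, subject_seed = all_seeds[i, 1],
                 session_seeds = all_seeds[i, -1])
  })
}
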