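# Small shared phantom fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## small, fast phantom spec for module tests (coarser than the defaults)
small_spec <- function(...) {
  phantom_spec(shape = c(28L, 28L, 28L), voxel_mm = 4, n_frames = 60, ...)
}

small_subject <- function() {
  fixture("small_subject", function() make_subject(small_spec(), 11L, c(21L, 31L)))
}

small_cohort <- function() {
  fixture("small_cohort", function() {
    make_cohort(small_spec(), n_subjects = 4L, base_seed = 7L)
  })
}
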