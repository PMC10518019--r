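# Shared phantom fixtures. The default-scale pipeline run is expensive, so
# it is computed once per test session and cached; small fixtures are built
# fresh where cheap.

.scmst_test_cache <- new.env(parent = emptyenv())

# a small phantom configuration for fast unit tests
small_phantom_config <- function(seed = 11) {
  phantom_config(
    n_embryos = 2, n_fovs_per_embryo = 1,
    volume_shape = c(8L, 96L, 96L), n_cells_per_fov = 12,
    rng_seed = seed
  )
}

# the default desk-scale acquisition used by the acceptance checks
default_phantom_config <- function(seed = 1) phantom_config(rng_seed = seed)

# one full default pipeline run, cached for the session
default_run <- function() {
  if (is.null(.scmst_test_cache$run)) {
    cfg <- pipeline_config(default_phantom_config(), write_images = FALSE)
    out <- file.path(tempdir(), "scmst-default-run")
    .scmst_test_cache$run <- suppressWarnings(
      run_pipeline(cfg, out, keep_truth = TRUE))
  }
  .scmst_test_cache$run
}

# simple synthetic volume with planted blobs for detector tests
planted_volume <- function(dim3 = c(12L, 64L, 64L), positions, amp = 100,
                           sigma = c(0.7, 1, 1), background = 10,
                           noise_sd = 0.5, seed = 5) {
  vol <- array(0, dim3)
  k <- scmst:::.psf_kernel(sigma)
  vol <- scmst:::.add_blobs_cpp(vol, matrix(as.integer(positions), ncol = 3),
                                rep(amp, nrow(positions)), k)
  withr::with_seed(seed, vol + background + rnorm(length(vol), 0, noise_sd))
}
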