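# Shared fixtures. Everything is generated in code; the expensive pieces
# (full-size lead field, default-condition pipeline runs) are computed once
# per test session and cached in an environment.

.fix <- new.env(parent = emptyenv())

# small geometry for unit tests: coarse grid, few electrodes, no holes
small_geometry <- function() {
  if (is.null(.fix$small)) {
    disc <- build_source_disc(grid_size = 24, fov_mm = 200, slice_z_mm = 18,
                              n_dipoles = NA,
                              source_sizes = c(20, 10, 12, 25))
    montage <- build_montage(16)
    lf <- compute_leadfield(montage, disc, truncation = 30)
    .fix$small <- list(disc = disc, montage = montage, leadfield = lf)
  }
  .fix$small
}

# full benchmark geometry (shared with the package-level cache)
full_geometry <- function() build_geometry(mfnc_config())

# one full-size default-condition study + analysis per seed, cached
default_run <- function(seed) {
  key <- paste0("run", seed)
  if (is.null(.fix[[key]])) {
    cfg <- mfnc_config()
    geo <- full_geometry()
    sim <- simulate_study(cfg, seed = seed, geometry = geo)
    res <- run_mfnc(sim$eeg, sim$fmri, geo$leadfield, geo$disc, cfg,
                    seed = seed + 500L)
    ea <- assign_truth_labels(res$eeg_components, geo$disc, cfg$eeg_sources,
                              geo$leadfield)
    fa <- assign_truth_labels(res$fmri_components, geo$disc,
                              cfg$fmri_sources)
    .fix[[key]] <- list(sim = sim, res = res, ea = ea, fa = fa,
                        score = score_run(res, sim$truth, ea, fa,
                                          cfg$eeg_sources, cfg$fmri_sources))
  }
  .fix[[key]]
}

# assert the free-energy trace of an inversion is non-decreasing (1e-8 slack
# relative to the trace magnitude)
expect_free_energy_monotone <- function(result) {
  fe <- result$free_energy
  if (length(fe) > 1) {
    slack <- 1e-8 * max(1, abs(fe[1]))
    expect_true(all(diff(fe) >= -slack),
                label = paste("free energy non-decreasing (min step",
                              format(min(diff(fe))), ")"))
  }
  invisible(result)
}
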