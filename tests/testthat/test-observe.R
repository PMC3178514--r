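test_that("gamma HRF kernel has the documented shape", {
  h <- gamma_hrf()
  expect_length(h$taps, 975)              # 13 x 1.5 s at 20 ms steps
  expect_equal(sum(h$taps), 1)
  expect_true(all(h$taps >= 0))
  # peak latency at the analytic gamma mode (shape - 1) * scale
  expect_equal((which.max(h$taps) - 1) * h$spacing, (6 - 1) * 0.9,
               tolerance = h$spacing / 4.5)
  # literal mode: exactly l taps, with a truncation warning
  expect_warning(hl <- gamma_hrf(13, mode = "literal"), "truncated")
  expect_length(hl$taps, 13)
  # convolving an impulse returns the kernel
  x <- c(1, rep(0, 2000))
  y <- stats::filter(c(rep(0, length(h$taps) - 1), x), h$taps,
                     method = "convolution", sides = 1)
  expect_equal(as.numeric(y[length(h$taps) - 1 + seq_along(h$taps)]),
               h$taps)
})

test_that("noise specification validates its fields", {
  ns <- noise_spec()
  expect_equal(ns$snr_meas_fmri, 0.2)
  expect_silent(noise_spec(Inf, Inf, Inf, Inf))
  expect_error(noise_spec(snr_phys_eeg = 0), "positive")
  expect_error(noise_spec(snr_meas_eeg = -1), "positive")
})

test_that("EEG rendering produces referenced trials of the right shape", {
  sg <- small_geometry()
  src <- simulate_sources(default_graph_spec(0.5), n_samples = 4000,
                          seed = 2)
  eeg <- render_eeg(src, sg$disc, sg$leadfield, noise_spec(),
                    n_trials = 40, trial_len = 55, seed = 3)
  expect_equal(dim(eeg$trials), c(40L, 16L, 55L))
  # average reference: channel mean at every sample is zero
  expect_lt(max(abs(apply(eeg$trials, c(1, 3), mean))), 1e-12)
  expect_error(render_eeg(src, sg$disc, sg$leadfield, noise_spec(),
                          n_trials = 80, trial_len = 55, seed = 3),
               "exceeds source length")
})

test_that("noiseless EEG lies in the projected-profile span", {
  sg <- small_geometry()
  src <- simulate_sources(default_graph_spec(0.5), n_samples = 4000,
                          seed = 4)
  ns <- noise_spec(snr_phys_eeg = Inf, snr_meas_eeg = Inf)
  eeg <- render_eeg(src, sg$disc, sg$leadfield, ns, n_trials = 10,
                    trial_len = 50, seed = 5)
  G <- vapply(sg$disc$source_masks[1:3],
              function(ix) rowSums(sg$leadfield$gain[, ix, drop = FALSE]),
              numeric(16))
  for (tr in c(1, 7)) {
    Y <- eeg$trials[tr, , ]
    resid <- Y - G %*% qr.solve(G, Y)
    expect_lt(max(abs(resid)), 1e-8)     # rank <= 3, exact unmixing
  }
})

test_that("EEG measurement noise matches its SNR and stays stream-stable", {
  sg <- small_geometry()
  src <- simulate_sources(default_graph_spec(0.5), n_samples = 18000,
                          seed = 6)
  y_clean <- render_eeg(src, sg$disc, sg$leadfield,
                        noise_spec(snr_meas_eeg = Inf), seed = 9)
  y_meas <- render_eeg(src, sg$disc, sg$leadfield,
                       noise_spec(snr_meas_eeg = 1), seed = 9)
  # the added noise has unit variance relative to the unit-global-SD
  # signal, minus the 1/n_channels removed by the average reference
  dn <- y_meas$trials - y_clean$trials
  expect_equal(var(as.numeric(dn)), 1 - 1 / 16, tolerance = 0.03)
  expect_equal(var(as.numeric(y_clean$trials)), 1, tolerance = 0.05)
  # toggling the physiological stage leaves the measurement draw identical
  a <- render_eeg(src, sg$disc, sg$leadfield,
                  noise_spec(snr_phys_eeg = Inf, snr_meas_eeg = 1), seed = 9)
  b <- render_eeg(src, sg$disc, sg$leadfield,
                  noise_spec(snr_phys_eeg = 5, snr_meas_eeg = 1), seed = 9)
  a_clean <- render_eeg(src, sg$disc, sg$leadfield,
                        noise_spec(snr_phys_eeg = Inf, snr_meas_eeg = Inf),
                        seed = 9)
  b_clean <- render_eeg(src, sg$disc, sg$leadfield,
                        noise_spec(snr_phys_eeg = 5, snr_meas_eeg = Inf),
                        seed = 9)
  expect_equal(a$trials - a_clean$trials, b$trials - b_clean$trials,
               tolerance = 1e-12)
})

test_that("fMRI rendering subsamples to the documented volume count", {
  sg <- small_geometry()
  src <- simulate_sources(default_graph_spec(0.5), n_samples = 18000,
                          seed = 7)
  fmri <- render_fmri(src, sg$disc, gamma_hrf(), noise_spec(), seed = 8)
  expect_equal(ncol(fmri$series), 240L)
  expect_equal(nrow(fmri$series), nrow(sg$disc$positions))
  expect_equal(fmri$tr_seconds, 1.5)
  # volume count = floor(T / subsample) for odd lengths too
  src2 <- simulate_sources(default_graph_spec(0.5), n_samples = 1234,
                           seed = 7)
  f2 <- render_fmri(src2, sg$disc, gamma_hrf(), noise_spec(), seed = 8)
  expect_equal(ncol(f2$series), floor(1234 / 75))
  # kernel spacing must match the neural sampling interval
  expect_error(render_fmri(src, sg$disc, gamma_hrf(neural_dt = 0.05),
                           noise_spec(), seed = 8),
               "does not match")
})

test_that("constant source gives a flat voxel series on the noiseless path", {
  sg <- small_geometry()
  src <- matrix(1, 4, 3000)
  ns <- noise_spec(snr_phys_fmri = Inf, snr_meas_fmri = Inf)
  f <- render_fmri(src, sg$disc, gamma_hrf(), ns, seed = 1)
  expect_lt(max(abs(f$series)), 1e-9)    # unit-sum kernel, constant in = 0 out
})

test_that("fMRI measurement noise is volume-referenced", {
  sg <- small_geometry()
  src <- simulate_sources(default_graph_spec(0.5), n_samples = 18000,
                          seed = 9)
  clean <- render_fmri(src, sg$disc, gamma_hrf(),
                       noise_spec(snr_meas_fmri = Inf), seed = 4)
  noisy <- render_fmri(src, sg$disc, gamma_hrf(),
                       noise_spec(snr_meas_fmri = 0.2), seed = 4)
  dn <- noisy$series - clean$series
  mv <- mean(apply(clean$series, 1, var))
  # noise variance ~ 5x the mean signal variance over the volume
  expect_equal(var(as.numeric(dn)) / mv, 5, tolerance = 0.1)
})
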