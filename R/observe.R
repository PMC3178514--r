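#' Noise specification for the observation models
#'
#' Signal-to-noise ratios are variance ratios (signal variance over noise
#' variance); `Inf` disables a noise stage. Physiological noise is added to
#' each source time course before spatial mixing; measurement noise is added
#' per channel (EEG) or per voxel (fMRI) after mixing and renormalization.
#'
#' @param snr_phys_eeg,snr_phys_fmri physiological SNR per modality
#'   (default 5).
#' @param snr_meas_eeg EEG measurement SNR (default 1).
#' @param snr_meas_fmri fMRI measurement SNR (default 0.2).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr_phys_eeg = 5, snr_phys_fmri = 5,
                       snr_meas_eeg = 1, snr_meas_fmri = 0.2) {
  vals <- c(snr_phys_eeg, snr_phys_fmri, snr_meas_eeg, snr_meas_fmri)
  if (any(!(vals > 0))) stop("all SNRs must be positive (Inf allowed)")
  structure(list(snr_phys_eeg = snr_phys_eeg, snr_phys_fmri = snr_phys_fmri,
                 snr_meas_eeg = snr_meas_eeg, snr_meas_fmri = snr_meas_fmri),
            class = "noise_spec")
}

.noise_sd <- function(snr) if (is.infinite(snr)) 0 else 1 / sqrt(snr)

.znorm <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Gamma hemodynamic response kernel
#'
#' Samples a gamma-density impulse response. In `"default"` mode the kernel
#' support is `l * tr` seconds (so the conventional 13 peristimulus TR-spaced
#' points at TR = 1.5 s give a 19.5 s support) sampled densely at the neural
#' sampling interval for convolution at the neural rate. `"literal"` mode
#' returns exactly `l` taps at `neural_dt` spacing. Taps are nonnegative and
#' normalized to unit sum.
#'
#' @param l kernel size parameter (default 13).
#' @param tr volume repeat time in seconds (default 1.5).
#' @param neural_dt neural sampling interval in seconds (default 0.02).
#' @param mode `"default"` or `"literal"` (see above).
#' @param shape,scale gamma parameters; defaults 6 and 0.9 s put the peak at
#'   the gamma mode (shape - 1) * scale = 4.5 s.
#' @return An object of class `hrf_kernel`: `taps`, `spacing`, `parameters`.
#' @export
gamma_hrf <- function(l = 13, tr = 1.5, neural_dt = 0.02,
                      mode = c("default", "literal"),
                      shape = 6, scale = 0.9) {
  mode <- match.arg(mode)
  stopifnot(l >= 1, neural_dt > 0, tr > 0)
  support <- if (mode == "default") l * tr else l * neural_dt
  if (support < (shape - 1) * scale)
    warning("HRF support (", support, " s) shorter than the gamma peak at ",
            (shape - 1) * scale, " s; kernel is truncated")
  n <- if (mode == "default") round(l * tr / neural_dt) else as.integer(l)
  t <- (seq_len(n) - 1) * neural_dt
  taps <- dgamma(t, shape = shape, scale = scale)
  taps <- taps / sum(taps)
  structure(list(taps = taps, spacing = neural_dt,
                 parameters = c(shape = shape, scale = scale),
                 mode = mode),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat("<hrf_kernel> ", length(x$taps), " taps @ ", x$spacing * 1000,
      " ms (gamma shape ", x$parameters["shape"], ", scale ",
      x$parameters["scale"], " s; peak ", signif(
        (which.max(x$taps) - 1) * x$spacing, 3), " s)\n", sep = "")
  invisible(x)
}

# derived, mutually independent RNG streams so that toggling one noise stage
# leaves the draws of the others bit-identical
.stage_seed <- function(seed, stage) (seed + stage * 1000003L) %% 2147483647L

#' Render scalp EEG trials from source dynamics
#'
#' Splits the EEG-visible source courses into equal trials keeping the first
#' `trial_len` samples of each, z-normalizes each source course per trial,
#' adds per-source Gaussian physiological noise, distributes each noisy
#' course uniformly over its dipole patch and projects through the lead
#' field. The scalp data are then renormalized by a single scalar (unit
#' global standard deviation — a channel-wise rescaling would distort the
#' topographies relative to the lead-field geometry), channel-wise
#' measurement noise is added, and the average reference is applied.
#'
#' @param sources a [simulate_sources()] result (or k x T matrix).
#' @param disc the [build_source_disc()] geometry.
#' @param leadfield the [compute_leadfield()] gain.
#' @param noise a [noise_spec()].
#' @param n_trials number of trials (default 40).
#' @param trial_len samples kept per trial (default 55, i.e. 1100 ms at
#'   20 ms sampling).
#' @param source_rows which source channels are EEG-visible (default 1:3).
#' @param seed random seed; physiological and measurement noise use
#'   independent derived streams.
#' @return An object of class `eeg_dataset`: `trials` (n_trials x channels x
#'   samples), `sample_rate`, `montage_labels`, `reference`.
#' @export
render_eeg <- function(sources, disc, leadfield, noise = noise_spec(),
                       n_trials = 40, trial_len = 55, source_rows = 1:3,
                       seed = 1) {
  S <- if (inherits(sources, "source_series")) sources$values else sources
  S <- S[source_rows, , drop = FALSE]
  ns <- nrow(S); Tt <- ncol(S)
  seg_len <- floor(Tt / n_trials)
  if (trial_len > seg_len)
    stop("requested segmentation exceeds source length: ", n_trials,
         " trials of ", trial_len, " samples need ", n_trials * trial_len,
         " > ", Tt, " available")
  # per-source summed lead-field column over the patch (uniform unit weight)
  G <- vapply(disc$source_masks[source_rows],
              function(ix) rowSums(leadfield$gain[, ix, drop = FALSE]),
              numeric(nrow(leadfield$gain)))
  ne <- nrow(G)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.stage_seed(seed, 1L))
  phys <- array(rnorm(n_trials * ns * trial_len, sd = 1), c(ns, trial_len, n_trials))
  set.seed(.stage_seed(seed, 2L))
  meas <- array(rnorm(n_trials * ne * trial_len, sd = 1), c(ne, trial_len, n_trials))

  sd_p <- .noise_sd(noise$snr_phys_eeg)
  sd_m <- .noise_sd(noise$snr_meas_eeg)
  trials <- array(0, c(n_trials, ne, trial_len))
  for (tr in seq_len(n_trials)) {
    seg <- S[, (tr - 1) * seg_len + seq_len(trial_len), drop = FALSE]
    seg <- t(apply(seg, 1, .znorm))    # per-trial source normalization
    seg <- seg + sd_p * phys[, , tr]
    trials[tr, , ] <- G %*% seg
  }
  trials <- trials / stats::sd(trials)  # single-scalar scalp renormalization
  for (tr in seq_len(n_trials)) {
    Y <- trials[tr, , ] + sd_m * meas[, , tr]
    Y <- sweep(Y, 2, colMeans(Y))      # average reference per sample
    trials[tr, , ] <- Y
  }
  structure(list(trials = trials,
                 sample_rate = if (inherits(sources, "source_series"))
                   sources$sample_rate else NA_real_,
                 montage_labels = rownames(leadfield$gain),
                 reference = "average",
                 source_rows = source_rows,
                 seed = seed),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  d <- dim(x$trials)
  cat("<eeg_dataset> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples (", x$reference, " reference)\n", sep = "")
  invisible(x)
}

#' Render voxel-wise BOLD series from source dynamics
#'
#' Convolves each fMRI-visible source course with the hemodynamic kernel,
#' z-normalizes, adds per-source physiological noise, forms voxel series as
#' patch-indicator weighted sums, subsamples every `subsample` steps (every
#' 75 neural steps of 20 ms gives TR = 1.5 s), z-normalizes per voxel, and
#' adds voxel-wise measurement noise.
#'
#' The patch weighting and subsampling commute, so voxel series are formed
#' after subsampling; the result is identical to subsampling full voxel
#' series.
#'
#' @param sources a [simulate_sources()] result (or k x T matrix).
#' @param disc the [build_source_disc()] geometry.
#' @param hrf a [gamma_hrf()] kernel sampled at the neural rate.
#' @param noise a [noise_spec()].
#' @param subsample neural steps per volume (default 75).
#' @param source_rows which source channels are fMRI-visible
#'   (default c(1, 3, 4)).
#' @param seed random seed (independent derived noise streams).
#' @return An object of class `fmri_dataset`: `series` (voxels x volumes),
#'   `tr_seconds`, `n_voxels`, `spatial_profiles` (voxels x sources truth
#'   indicator maps, simulation provenance).
#' @export
render_fmri <- function(sources, disc, hrf = gamma_hrf(),
                        noise = noise_spec(), subsample = 75,
                        source_rows = c(1, 3, 4), seed = 1) {
  S <- if (inherits(sources, "source_series")) sources$values else sources
  srate <- if (inherits(sources, "source_series")) sources$sample_rate else 1 / hrf$spacing
  if (abs(hrf$spacing - 1 / srate) > 1e-9)
    stop("HRF tap spacing (", hrf$spacing, " s) does not match the neural ",
         "sampling interval (", 1 / srate, " s)")
  stopifnot(subsample >= 1)
  S <- S[source_rows, , drop = FALSE]
  ns <- nrow(S); Tt <- ncol(S)
  l <- length(hrf$taps)
  conv1 <- function(x) {
    # steady-state boundary: pre-recording activity held at its initial
    # level, so the kernel's ramp-in does not fabricate a transient
    y <- stats::filter(c(rep(x[1], l - 1), x), hrf$taps,
                       method = "convolution", sides = 1)
    as.numeric(y[l - 1 + seq_len(Tt)])
  }
  H <- t(apply(S, 1, conv1))
  H <- t(apply(H, 1, .znorm))

  n_vol <- floor(Tt / subsample)
  idx <- seq_len(n_vol) * subsample
  nd <- nrow(disc$positions)
  P <- matrix(0, nd, ns)
  for (s in seq_len(ns)) P[disc$source_masks[[source_rows[s]]], s] <- 1

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.stage_seed(seed, 3L))
  phys <- matrix(rnorm(ns * Tt), ns, Tt)
  set.seed(.stage_seed(seed, 4L))
  meas <- matrix(rnorm(nd * n_vol), nd, n_vol)

  H <- H + .noise_sd(noise$snr_phys_fmri) * phys
  V <- P %*% H[, idx, drop = FALSE]
  V <- t(apply(V, 1, .znorm))          # background voxels stay flat zero
  # scanner noise is spatially uniform: its variance references the mean
  # signal variance over the acquired volume (active patches cover ~9% of
  # the disc), not each voxel's own normalized variance
  mv <- mean(apply(V, 1, stats::var))
  sd_m <- if (is.infinite(noise$snr_meas_fmri)) 0
          else sqrt(mv / noise$snr_meas_fmri)
  V <- V + sd_m * meas
  structure(list(series = V,
                 tr_seconds = subsample * hrf$spacing,
                 n_voxels = nd,
                 spatial_profiles = P,
                 source_rows = source_rows,
                 seed = seed),
            class = "fmri_dataset")
}

#' @export
print.fmri_dataset <- function(x, ...) {
  cat("<fmri_dataset> ", nrow(x$series), " voxels x ", ncol(x$series),
      " volumes (TR ", x$tr_seconds, " s)\n", sep = "")
  invisible(x)
}
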