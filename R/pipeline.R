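#' Analysis configuration
#'
#' Collects every tunable of the benchmark and pipeline with its default:
#' geometry (70 x 70 grid, 200 mm FOV, 18 mm slice, radii 0.87/0.89/1,
#' 62 electrodes), dynamics (coupling 0.5, 18000 samples at 50 Hz, 1000
#' burn-in), observation (40 trials x 55 samples, physiological SNR 5 per
#' modality, measurement SNR 1 and 0.2, gamma HRF with l = 13 at TR 1.5 s,
#' subsampling 75), decomposition (20 FastICA restarts, similarity 0.8,
#' occurrence 0.5), causality (BIC search to order 10, nominal level 0.01)
#' and matching (z threshold 3, map quantile 0.01).
#'
#' @param ... named overrides of any default.
#' @return A named list of class `mfnc_config`.
#' @export
mfnc_config <- function(...) {
  cfg <- list(
    grid_size = 70, fov_mm = 200, slice_z_mm = 18,
    sphere_radii = c(0.87, 0.89, 1), n_dipoles = 2452,
    conductivities = c(1, 1 / 80, 1), n_electrodes = 62,
    coupling = 0.5, n_samples = 18000, burn_in = 1000, sample_rate = 50,
    innovations = "laplace",
    snr_phys_eeg = 5, snr_phys_fmri = 5, snr_meas_eeg = 1,
    snr_meas_fmri = 0.2,
    n_trials = 40, trial_len = 55,
    hrf_l = 13, hrf_tr = 1.5, hrf_shape = 6, hrf_scale = 0.9,
    subsample = 75,
    eeg_sources = 1:3, fmri_sources = c(1, 3, 4),
    ica_runs = 20, ica_mode = "symmetric", ica_max_iter = 1000,
    ica_tol = 1e-4,
    ica_reduce_eeg = "auto", ica_reduce_fmri = "auto",
    similarity_threshold = 0.8, min_occurrence = 0.5,
    exclude_eeg = integer(0), exclude_fmri = integer(0),
    p_max = 10, alpha_nominal = 0.01,
    z_threshold = 3, map_quantile = 0.01,
    reml_tol = 1e-6, reml_max_iter = 256)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "mfnc_config"
  cfg
}

#' Build (and cache) the benchmark geometry
#'
#' The source disc, montage and analytic lead field are fully deterministic
#' given the configuration, so they are computed once per session and
#' cached.
#'
#' @param config an [mfnc_config()].
#' @return List with `disc`, `montage`, `leadfield`.
#' @export
build_geometry <- function(config = mfnc_config()) {
  key <- paste(c(config$grid_size, config$fov_mm, config$slice_z_mm,
                 config$sphere_radii, config$n_dipoles,
                 config$conductivities, config$n_electrodes),
               collapse = "|")
  hit <- .mfnc_cache[[key]]
  if (!is.null(hit)) return(hit)
  disc <- build_source_disc(grid_size = config$grid_size,
                            fov_mm = config$fov_mm,
                            slice_z_mm = config$slice_z_mm,
                            sphere_radii = config$sphere_radii,
                            n_dipoles = config$n_dipoles)
  montage <- build_montage(config$n_electrodes)
  lf <- compute_leadfield(montage, disc,
                          conductivities = config$conductivities)
  out <- list(disc = disc, montage = montage, leadfield = lf)
  .mfnc_cache[[key]] <- out
  out
}

#' Generate one synthetic EEG-fMRI study
#'
#' Runs the full generative chain: coupled VAR source dynamics, scalp EEG
#' trials through the analytic head model, and voxel-wise BOLD through the
#' gamma HRF, at the configured coupling and noise levels.
#'
#' @param config an [mfnc_config()]; `coupling`, `snr_phys_eeg` and
#'   `snr_phys_fmri` set the study condition.
#' @param seed master seed for dynamics and both observation stages.
#' @param geometry optional precomputed [build_geometry()] result.
#' @return List with `sources`, `eeg`, `fmri`, `disc`, `montage`,
#'   `leadfield`, `truth` (the generating [causal_graph_spec()]) and `config`.
#' @export
simulate_study <- function(config = mfnc_config(), seed = 1,
                           geometry = NULL) {
  if (is.null(geometry)) geometry <- build_geometry(config)
  spec <- default_graph_spec(config$coupling)
  src <- simulate_sources(spec, n_samples = config$n_samples,
                          burn_in = config$burn_in, seed = seed,
                          sample_rate = config$sample_rate,
                          innovations = config$innovations)
  noise <- noise_spec(config$snr_phys_eeg, config$snr_phys_fmri,
                      config$snr_meas_eeg, config$snr_meas_fmri)
  hrf <- gamma_hrf(config$hrf_l, config$hrf_tr, 1 / config$sample_rate,
                   shape = config$hrf_shape, scale = config$hrf_scale)
  eeg <- render_eeg(src, geometry$disc, geometry$leadfield, noise,
                    n_trials = config$n_trials,
                    trial_len = config$trial_len,
                    source_rows = config$eeg_sources, seed = seed)
  fmri <- render_fmri(src, geometry$disc, hrf, noise,
                      subsample = config$subsample,
                      source_rows = config$fmri_sources, seed = seed)
  c(list(sources = src, eeg = eeg, fmri = fmri, truth = spec,
         config = config, seed = seed), geometry)
}

# channels x (trials * len) concatenation of an eeg_dataset
.eeg_concat <- function(eeg) {
  d <- dim(eeg$trials)
  mat <- matrix(aperm(eeg$trials, c(2, 3, 1)), d[2], d[3] * d[1])
  mat
}

# split component time courses back into the trial structure for GCA
.courses_to_trials <- function(tc, n_trials, trial_len) {
  lapply(seq_len(n_trials), function(tr)
    tc[, (tr - 1) * trial_len + seq_len(trial_len), drop = FALSE])
}

.ica_consensus <- function(data, modality, config, seed) {
  independence <- if (modality == "eeg") "time" else "space"
  n_reduce <- if (modality == "eeg") config$ica_reduce_eeg
              else config$ica_reduce_fmri
  wh <- ica_whiten(data, independence = independence, n_reduce = n_reduce)
  runs <- lapply(seq_len(config$ica_runs), function(i)
    tryCatch(spatial_ica(data, mode = config$ica_mode, seed = seed + 11L * i,
                         max_iter = config$ica_max_iter,
                         tol = config$ica_tol, whitening = wh),
             error = function(e) NULL))
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) < 2)
    stop("fewer than 2 of ", config$ica_runs, " FastICA restarts converged")
  cons <- consensus_components(runs, data = data,
                               similarity_threshold = config$similarity_threshold,
                               min_occurrence = config$min_occurrence)
  cons$modality <- modality
  cons
}

#' Run the full multimodal FNC analysis
#'
#' Per modality: multi-restart deflation spatial ICA with consensus
#' clustering, optional manual screening, BIC order selection and
#' Bonferroni-corrected conditional Granger causality on the component time
#' courses; then NESOI matching of EEG topographies to fMRI spatial priors,
#' and graph metrics on both causal graphs. Any stage failure is propagated
#' with the stage name.
#'
#' @param eeg an [render_eeg()] dataset.
#' @param fmri an [render_fmri()] dataset.
#' @param leadfield the [compute_leadfield()] gain used for inversion.
#' @param disc the [build_source_disc()] geometry.
#' @param config an [mfnc_config()].
#' @param seed seed driving the ICA restarts.
#' @return An object of class `mfnc_result` with `eeg_components`,
#'   `fmri_components`, `eeg_graph`, `fmri_graph`, `eeg_order`,
#'   `fmri_order`, `match`, `inversions`, `eeg_metrics`, `fmri_metrics`,
#'   `provenance`.
#' @export
run_mfnc <- function(eeg, fmri, leadfield, disc, config = mfnc_config(),
                     seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("mFNC stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  eeg_mat <- .eeg_concat(eeg)
  eeg_comp <- stage("decompose-eeg", {
    cc <- .ica_consensus(eeg_mat, "eeg", config, seed)
    screen_components(cc, config$exclude_eeg)
  })
  fmri_comp <- stage("decompose-fmri", {
    cc <- .ica_consensus(fmri$series, "fmri", config, seed + 5000L)
    screen_components(cc, config$exclude_fmri)
  })
  if (nrow(eeg_comp$spatial_maps) < 2)
    stop("mFNC stage 'decompose-eeg' failed: need at least 2 components ",
         "for causality analysis, got ", nrow(eeg_comp$spatial_maps),
         call. = FALSE)
  if (nrow(fmri_comp$spatial_maps) < 2)
    stop("mFNC stage 'decompose-fmri' failed: need at least 2 components ",
         "for causality analysis, got ", nrow(fmri_comp$spatial_maps),
         call. = FALSE)

  d <- dim(eeg$trials)
  eeg_trials <- .courses_to_trials(eeg_comp$time_courses, d[1], d[3])
  eeg_order <- stage("gca-eeg", select_order_bic(eeg_trials, config$p_max))
  eeg_graph <- stage("gca-eeg", gc_edges(eeg_trials, eeg_order,
                                         config$alpha_nominal))
  fmri_order <- stage("gca-fmri",
                      select_order_bic(fmri_comp$time_courses, config$p_max))
  fmri_graph <- stage("gca-fmri", gc_edges(fmri_comp$time_courses, fmri_order,
                                           config$alpha_nominal))

  nesoi <- stage("nesoi", {
    priors <- build_prior_components(fmri_comp, disc,
                                     z_threshold = config$z_threshold)
    proj <- project_priors(priors, leadfield)
    inv <- lapply(seq_len(nrow(eeg_comp$spatial_maps)), function(i)
      reml_invert(eeg_comp$spatial_maps[i, ], leadfield, proj,
                  tol = config$reml_tol, max_iter = config$reml_max_iter))
    list(priors = priors,
         inversions = inv,
         match = match_networks(inv, n_fmri = nrow(fmri_comp$spatial_maps)))
  })

  structure(list(eeg_components = eeg_comp, fmri_components = fmri_comp,
                 eeg_graph = eeg_graph, fmri_graph = fmri_graph,
                 eeg_order = eeg_order, fmri_order = fmri_order,
                 match = nesoi$match, inversions = nesoi$inversions,
                 priors = nesoi$priors,
                 eeg_metrics = graph_metrics(eeg_graph),
                 fmri_metrics = graph_metrics(fmri_graph),
                 provenance = list(seed = seed, config = config)),
            class = "mfnc_result")
}

#' @export
print.mfnc_result <- function(x, ...) {
  cat("<mfnc_result>\n")
  cat("  EEG : ", nrow(x$eeg_components$spatial_maps),
      " components, VAR order ", as.integer(x$eeg_order), ", ",
      sum(x$eeg_graph$adjacency), " edge(s)\n", sep = "")
  cat("  fMRI: ", nrow(x$fmri_components$spatial_maps),
      " components, VAR order ", as.integer(x$fmri_order), ", ",
      sum(x$fmri_graph$adjacency), " edge(s)\n", sep = "")
  cat("  matching:\n")
  print(x$match)
  invisible(x)
}

#' Assign components to ground-truth sources
#'
#' Scores each component map against each truth source profile by absolute
#' spatial correlation (EEG topographies against forward-projected profiles,
#' fMRI maps against the voxel profiles) and assigns greedily best-first
#' under injectivity; components left over are unassigned (`NA`).
#'
#' @param components a `component_set`.
#' @param disc the geometry holding the truth patches.
#' @param sources which truth sources are candidates (e.g. `1:3` for EEG).
#' @param leadfield supply to compare in channel space (EEG); omit for voxel
#'   space (fMRI).
#' @param min_correlation assignments below this absolute correlation are
#'   not made (a duplicate component whose best source is taken stays
#'   unassigned instead of grabbing an unrelated one).
#' @return Integer vector: truth source index per component (NA =
#'   unassigned); correlation matrix attached as attribute `"correlations"`.
#' @export
assign_truth_labels <- function(components, disc, sources,
                                leadfield = NULL, min_correlation = 0.1) {
  profiles <- vapply(disc$source_masks[sources], function(ix) {
    v <- numeric(nrow(disc$positions)); v[ix] <- 1; v
  }, numeric(nrow(disc$positions)))
  if (!is.null(leadfield)) {
    G <- if (inherits(leadfield, "leadfield")) leadfield$gain else leadfield
    profiles <- G %*% profiles
  }
  maps <- components$spatial_maps
  if (nrow(maps) == 0) return(integer(0))
  co <- abs(stats::cor(t(maps), profiles))
  co[!is.finite(co)] <- 0
  assign <- rep(NA_integer_, nrow(maps))
  used <- logical(length(sources))
  repeat {
    co_open <- co
    co_open[!is.na(assign), ] <- -1
    co_open[, used] <- -1
    if (all(co_open < min_correlation)) break
    best <- which(co_open == max(co_open), arr.ind = TRUE)[1, ]
    assign[best[1]] <- sources[best[2]]
    used[best[2]] <- TRUE
    if (!anyNA(assign) || all(used)) break
  }
  attr(assign, "correlations") <- co
  assign
}

#' Score one reconstruction against the ground truth
#'
#' Two-step scoring. Step 1 (classification): the component-to-source
#' assignments must cover each modality's visible sources exactly, the NESOI
#' matching must pair the EEG and fMRI components of each jointly visible
#' source, flag the EEG-only source's component EEG-specific, and leave the
#' fMRI-only source's component fMRI-specific. Step 2 (edges): truth edges
#' are evaluated over the modality-visible node subsets, a true edge counts
#' as detected when either modality shows it between correctly classified
#' components (union bookkeeping: a jointly visible edge is a single truth
#' item), and any detected edge absent from the truth counts against
#' specificity. A run failing step 1 contributes zero sensitivity and every
#' detected edge counts as a false alarm.
#'
#' @param result an [run_mfnc()] result.
#' @param truth the generating [causal_graph_spec()].
#' @param eeg_assign,fmri_assign assignments from [assign_truth_labels()].
#' @param eeg_sources,fmri_sources the visible source sets.
#' @return List with `classification_ok`, `sensitivity`, `specificity`,
#'   `union_exact` (TRUE when the detected union graph equals the visible
#'   truth exactly) and the confusion counts.
#' @export
score_run <- function(result, truth, eeg_assign, fmri_assign,
                      eeg_sources = 1:3, fmri_sources = c(1, 3, 4)) {
  E <- edge_set(truth)
  vis_edge <- function(a, b, sources) (a %in% sources) && (b %in% sources)
  truth_edges <- E[apply(E, 1, function(e)
    vis_edge(e[1], e[2], eeg_sources) || vis_edge(e[1], e[2], fmri_sources)),
    , drop = FALSE]
  all_sources <- sort(unique(c(eeg_sources, fmri_sources)))
  pairs <- expand.grid(from = all_sources, to = all_sources)
  pairs <- pairs[pairs$from != pairs$to, ]
  visible <- apply(pairs, 1, function(e)
    vis_edge(e[1], e[2], eeg_sources) || vis_edge(e[1], e[2], fmri_sources))
  pairs <- pairs[visible, ]
  is_truth <- apply(pairs, 1, function(e)
    any(truth_edges[, 1] == e[1] & truth_edges[, 2] == e[2]))

  class_ok <- .classification_ok(result, eeg_assign, fmri_assign,
                                 eeg_sources, fmri_sources)

  det_in <- function(graph, assign, a, b) {
    ia <- which(assign == a); ib <- which(assign == b)
    length(ia) == 1 && length(ib) == 1 && graph$adjacency[ib, ia]
  }
  detected <- apply(pairs, 1, function(e) {
    (vis_edge(e[1], e[2], eeg_sources) &&
       det_in(result$eeg_graph, eeg_assign, e[1], e[2])) ||
    (vis_edge(e[1], e[2], fmri_sources) &&
       det_in(result$fmri_graph, fmri_assign, e[1], e[2]))
  })

  n_true <- sum(is_truth); n_non <- sum(!is_truth)
  if (class_ok) {
    tp <- sum(detected & is_truth)
    fp <- sum(detected & !is_truth)
    sens <- if (n_true > 0) tp / n_true else NA_real_
    spec <- if (n_non > 0) (n_non - fp) / n_non else NA_real_
    union_exact <- all(detected == is_truth)
  } else {
    # every reported edge is a false alarm when the grouping itself is wrong
    n_det <- sum(result$eeg_graph$adjacency) + sum(result$fmri_graph$adjacency)
    tp <- 0L; fp <- min(n_det, n_non)
    sens <- 0
    spec <- if (n_non > 0) (n_non - fp) / n_non else NA_real_
    union_exact <- FALSE
  }
  list(classification_ok = class_ok, sensitivity = sens, specificity = spec,
       union_exact = union_exact,
       tp = tp, fp = fp, n_true_edges = n_true, n_non_edges = n_non)
}

.classification_ok <- function(result, eeg_assign, fmri_assign,
                               eeg_sources, fmri_sources) {
  ok_cover <- function(assign, sources)
    length(assign) == length(sources) && !anyNA(assign) &&
      setequal(assign, sources)
  if (!ok_cover(eeg_assign, eeg_sources) ||
      !ok_cover(fmri_assign, fmri_sources)) return(FALSE)
  common <- intersect(eeg_sources, fmri_sources)
  for (s in common) {
    ie <- which(eeg_assign == s); im <- which(fmri_assign == s)
    m <- result$match$match[ie]
    if (is.na(m) || m != im) return(FALSE)
  }
  for (s in setdiff(eeg_sources, fmri_sources)) {
    if (!is.na(result$match$match[which(eeg_assign == s)])) return(FALSE)
  }
  for (s in setdiff(fmri_sources, eeg_sources)) {
    if (!(which(fmri_assign == s) %in% result$match$fmri_specific))
      return(FALSE)
  }
  TRUE
}

#' Monte-Carlo robustness grid
#'
#' For every combination of coupling strength and modality-wise
#' physiological SNR, generates `replicates` independent studies, runs the
#' full pipeline, scores each run by the two-step procedure and aggregates
#' mean sensitivity, mean specificity and the classification-success rate.
#' Per-replicate seeds are derived arithmetically from the master seed, so
#' results are independent of execution order and fully reproducible.
#' Replicate-level failures are caught, logged and scored as failures, not
#' fatal.
#'
#' @param c_values coupling strengths (full study grid: 0.1, 0.3, 0.5, 0.7).
#' @param snr_eeg_values,snr_fmri_values physiological SNR axes (full study
#'   grid: Inf, 10, 5, 3.3, 2.5, 2).
#' @param replicates per-cell replicate count.
#' @param seed master seed.
#' @param config an [mfnc_config()]; the default uses 5 ICA restarts per
#'   modality for tractable grid sweeps.
#' @return An object of class `mfnc_eval`: `cells` (per-cell summary
#'   tibble), `replicates` (per-replicate detail tibble), `config`, `seed`.
#' @export
mc_grid <- function(c_values = c(0.1, 0.3, 0.5, 0.7),
                    snr_eeg_values = c(Inf, 10, 5, 3.3, 2.5, 2),
                    snr_fmri_values = c(Inf, 10, 5, 3.3, 2.5, 2),
                    replicates = 32, seed = 1,
                    config = mfnc_config(ica_runs = 5)) {
  stopifnot(replicates >= 1)
  geometry <- build_geometry(config)
  grid <- expand.grid(c = c_values, snr_eeg = snr_eeg_values,
                      snr_fmri = snr_fmri_values)
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    cfg <- config
    cfg$coupling <- grid$c[cell]
    cfg$snr_phys_eeg <- grid$snr_eeg[cell]
    cfg$snr_phys_fmri <- grid$snr_fmri[cell]
    for (rep in seq_len(replicates)) {
      seed_r <- (seed + 104729 * cell + 7919 * rep) %% 2147483647
      sc <- tryCatch({
        sim <- simulate_study(cfg, seed = seed_r, geometry = geometry)
        res <- run_mfnc(sim$eeg, sim$fmri, geometry$leadfield,
                        geometry$disc, cfg, seed = seed_r)
        ea <- assign_truth_labels(res$eeg_components, geometry$disc,
                                  cfg$eeg_sources, geometry$leadfield)
        fa <- assign_truth_labels(res$fmri_components, geometry$disc,
                                  cfg$fmri_sources)
        c(score_run(res, sim$truth, ea, fa, cfg$eeg_sources,
                    cfg$fmri_sources),
          list(error = NA_character_))
      }, error = function(e)
        list(classification_ok = FALSE, sensitivity = 0,
             specificity = NA_real_, union_exact = FALSE,
             tp = NA_integer_, fp = NA_integer_,
             n_true_edges = NA_integer_, n_non_edges = NA_integer_,
             error = conditionMessage(e)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        c = grid$c[cell], snr_eeg = grid$snr_eeg[cell],
        snr_fmri = grid$snr_fmri[cell], replicate = rep, seed = seed_r,
        classification_ok = sc$classification_ok,
        sensitivity = sc$sensitivity, specificity = sc$specificity,
        union_exact = sc$union_exact, error = sc$error)
    }
  }
  detail <- do.call(rbind, rows)
  cells <- do.call(rbind, lapply(split(detail,
      list(detail$c, detail$snr_eeg, detail$snr_fmri), drop = TRUE),
    function(d) tibble::tibble(
      c = d$c[1], snr_eeg = d$snr_eeg[1], snr_fmri = d$snr_fmri[1],
      n = nrow(d),
      mean_sensitivity = mean(d$sensitivity, na.rm = TRUE),
      mean_specificity = mean(d$specificity, na.rm = TRUE),
      classification_rate = mean(d$classification_ok),
      union_exact_rate = mean(d$union_exact),
      n_failed = sum(!is.na(d$error)))))
  cells <- cells[order(cells$c, cells$snr_eeg, cells$snr_fmri), ]
  structure(list(cells = cells, replicates = detail, config = config,
                 seed = seed),
            class = "mfnc_eval")
}

#' @export
print.mfnc_eval <- function(x, ...) {
  cat("<mfnc_eval> ", nrow(x$cells), " cell(s) x ", x$cells$n[1],
      " replicate(s), master seed ", x$seed, "\n", sep = "")
  print(x$cells, n = nrow(x$cells))
  invisible(x)
}

#' @describeIn mc_grid tidy per-cell summary table.
#' @param x an `mfnc_eval`.
#' @param ... unused.
#' @export
tidy.mfnc_eval <- function(x, ...) x$cells

#' @describeIn mc_grid one-row overall summary.
#' @export
glance.mfnc_eval <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells),
                 n_replicates = nrow(x$replicates),
                 mean_sensitivity = mean(x$cells$mean_sensitivity),
                 mean_specificity = mean(x$cells$mean_specificity),
                 n_failed = sum(x$cells$n_failed))
}

#' @describeIn mc_grid sensitivity/specificity surfaces as line plots
#'   against EEG SNR, faceted by fMRI SNR, colored by coupling.
#' @param object an `mfnc_eval`.
#' @export
autoplot.mfnc_eval <- function(object, ...) {
  d <- object$cells
  d <- rbind(
    tibble::tibble(c = d$c, snr_eeg = d$snr_eeg, snr_fmri = d$snr_fmri,
                   measure = "sensitivity", value = d$mean_sensitivity),
    tibble::tibble(c = d$c, snr_eeg = d$snr_eeg, snr_fmri = d$snr_fmri,
                   measure = "specificity", value = d$mean_specificity))
  d$snr_eeg_f <- factor(d$snr_eeg, levels = sort(unique(d$snr_eeg)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$snr_eeg_f, y = .data$value,
                                  group = factor(.data$c),
                                  colour = factor(.data$c))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(.data$measure ~ .data$snr_fmri,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "EEG physiological SNR", y = NULL,
                  colour = "coupling c") +
    ggplot2::theme_minimal()
}
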