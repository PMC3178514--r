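#' @name nesoi
#' @title Network-based source imaging (NESOI)
#'
#' @description
#' Each EEG component topography `Y` (one channel vector) is inverted under
#' the two-level hierarchical Gaussian model
#' `Y = X Phi + e1`, `e1 ~ N(0, g0 I)`, `Phi ~ N(0, sum_i g_i Q_i)`,
#' where the covariance components `Q_i` are built from the fMRI component
#' maps (diagonal in the squared z-scored, thresholded map) plus one
#' aggregated multiple-sparse-prior (MSP) component of smooth patches
#' covering the source space the fMRI maps leave uncovered. The nonnegative
#' hyperparameters `g` are estimated by restricted maximum likelihood via
#' EM updates on the sensor-space second moment, which maximize the
#' variational free energy (a lower bound on the log-evidence)
#' monotonically. The trace-weighted normalized hyperparameter profile of
#' each EEG component identifies its supporting fMRI network, or flags it
#' EEG-specific when the MSP component wins.
NULL

#' Build covariance prior components from fMRI maps
#'
#' Per fMRI component map: z-score over voxels, zero entries with
#' `|z| < z_threshold`, and take `Q = diag(z^2)` on the dipole grid (voxel
#' and dipole grids are in registration). An aggregated MSP component —
#' Gaussian-smoothed indicator patches spanning all dipoles not covered by
#' any fMRI prior, summed into a single low-rank `Q = G G'` — guarantees the
#' priors sample the whole source space.
#'
#' @param fmri_maps a `component_set` (fMRI) or n_comp x voxels matrix.
#' @param disc the [build_source_disc()] geometry (for patch smoothing
#'   distances).
#' @param z_threshold activation threshold on |z| (default 3).
#' @param msp add the complement MSP component (default TRUE).
#' @param patch_sigma spatial std-dev of the MSP patches in normalized units
#'   (default 0.06, about 6 mm).
#' @param patch_stride keep every `patch_stride`-th uncovered dipole as a
#'   patch center (default 8).
#' @return A list of `prior_component` objects: fields `label`, `type`
#'   (`"fmri"`/`"msp"`), `diag` (diagonal of Q) or `factor` (G with
#'   `Q = G G'`), `coverage` (dipole support), `trace`.
#' @export
build_prior_components <- function(fmri_maps, disc, z_threshold = 3,
                                   msp = TRUE, patch_sigma = 0.06,
                                   patch_stride = 8) {
  maps <- if (inherits(fmri_maps, "component_set")) fmri_maps$spatial_maps
          else as.matrix(fmri_maps)
  nd <- nrow(disc$positions)
  if (ncol(maps) != nd)
    stop("voxel dimension of the maps (", ncol(maps),
         ") does not match the dipole grid (", nd, ")")
  priors <- list()
  for (i in seq_len(nrow(maps))) {
    z <- .znorm(maps[i, ])
    z[abs(z) < z_threshold] <- 0
    if (all(z == 0)) {
      warning("fMRI component ", i, " has no supra-threshold voxels; dropped")
      next
    }
    priors[[length(priors) + 1]] <- structure(
      list(label = paste0("fMRI-", i), type = "fmri", index = i,
           diag = z^2, factor = NULL, coverage = which(z != 0),
           trace = sum(z^2)),
      class = "prior_component")
  }
  if (msp) {
    covered <- sort(unique(unlist(lapply(priors, `[[`, "coverage"))))
    uncovered <- setdiff(seq_len(nd), covered)
    if (length(uncovered) == 0) {
      warning("fMRI priors cover every dipole; MSP component omitted")
    } else {
      centers <- uncovered[seq(1, length(uncovered), by = patch_stride)]
      pos <- disc$positions
      d2 <- outer(rowSums(pos[uncovered, 1:2, drop = FALSE]^2),
                  rowSums(pos[centers, 1:2, drop = FALSE]^2), "+") -
            2 * pos[uncovered, 1:2, drop = FALSE] %*%
                t(pos[centers, 1:2, drop = FALSE])
      Gu <- exp(-pmax(d2, 0) / (2 * patch_sigma^2))
      Gu <- sweep(Gu, 2, sqrt(colSums(Gu^2)), "/")
      G <- matrix(0, nd, ncol(Gu))
      G[uncovered, ] <- Gu
      priors[[length(priors) + 1]] <- structure(
        list(label = "MSP", type = "msp", index = NA_integer_,
             diag = NULL, factor = G, coverage = uncovered,
             trace = sum(G^2)),
        class = "prior_component")
    }
  }
  if (length(priors) == 0) stop("no usable prior component")
  priors
}

# sensor-space projections P_i = X Q_i X' with eigen factorizations for the
# EM updates; shared across the inversions of all EEG components
.project_priors <- function(priors, X) {
  lapply(priors, function(pr) {
    P <- if (!is.null(pr$diag)) {
      tcrossprod(X * rep(sqrt(pr$diag), each = nrow(X)))
    } else {
      tcrossprod(X %*% pr$factor)
    }
    P <- (P + t(P)) / 2
    e <- eigen(P, symmetric = TRUE)
    r <- sum(e$values > max(e$values) * 1e-10)
    list(prior = pr, P = P, trace = sum(diag(P)), rank = max(r, 1L))
  })
}

#' Invert one EEG topography by ReML
#'
#' Maximizes the free energy
#' `F = -1/2 [ ln det C + Y' C^{-1} Y + e ln 2 pi ]`, with
#' `C = g0 I + sum_i g_i X Q_i X'`, over nonnegative hyperparameters by EM
#' (expectation over the latent per-component source amplitudes), which
#' increases F monotonically. Returns the hyperparameters, the free-energy
#' trace and the posterior mean source distribution
#' `Phi = C2 X' C^{-1} Y`.
#'
#' @param Y channel topography (length-e vector).
#' @param X lead-field gain (e x d matrix) or a `leadfield` object.
#' @param priors list from [build_prior_components()].
#' @param tol relative free-energy convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 256).
#' @return An object of class `reml_result`: `gamma` (named, sensor noise
#'   first), `free_energy` (per-iteration trace), `posterior_mean`,
#'   `converged`, `trace_P` (sensor-space trace per prior, for
#'   [match_networks()]).
#' @export
reml_invert <- function(Y, X, priors, tol = 1e-6, max_iter = 256) {
  if (inherits(X, "leadfield")) X <- X$gain
  Y <- as.numeric(Y)
  e <- nrow(X)
  if (length(Y) != e) stop("topography length does not match lead-field rows")
  if (length(priors) < 1) stop("need at least one prior component")
  proj <- if (!is.null(attr(priors, "projected"))) priors
          else .project_priors(priors, X)
  m <- length(proj)
  Ps <- c(list(diag(e)), lapply(proj, `[[`, "P"))
  ranks <- c(e, vapply(proj, `[[`, 1L, "rank"))
  traces <- c(e, vapply(proj, function(p) p$trace, 1))

  y2 <- sum(Y^2)
  if (y2 == 0) {
    gamma <- c(noise = 0, setNames(numeric(m),
                                   vapply(proj, function(p) p$prior$label, "")))
    return(structure(list(gamma = gamma, free_energy = numeric(0),
                          posterior_mean = numeric(ncol(X)),
                          converged = TRUE,
                          trace_P = traces[-1], proj = proj),
                     class = "reml_result"))
  }
  # scale-covariant initialization: equal share of the data power per
  # component, in each component's own sensor-space units
  gamma <- (y2 / e) / (traces / e) / (m + 1)
  Fs <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- matrix(0, e, e)
    for (i in seq_along(Ps)) C <- C + gamma[i] * Ps[[i]]
    ch <- tryCatch(chol(C), error = function(err) NULL)
    if (is.null(ch)) stop("model covariance not positive definite at ",
                          "iteration ", it)
    Cinv <- chol2inv(ch)
    CiY <- Cinv %*% Y
    Fcur <- -0.5 * (2 * sum(log(diag(ch))) + sum(Y * CiY) + e * log(2 * pi))
    if (!is.finite(Fcur))
      stop("non-finite free energy at iteration ", it,
           "; gamma = ", paste(signif(gamma, 4), collapse = ", "))
    Fs <- c(Fs, Fcur)
    if (it > 1 && abs(Fs[it] - Fs[it - 1]) <= tol * abs(Fs[it - 1])) {
      converged <- TRUE
      break
    }
    # EM update: gamma_i <- gamma_i - gamma_i^2 / r_i *
    #            (tr(Cinv P_i) - Y' Cinv P_i Cinv Y)
    for (i in seq_along(Ps)) {
      t1 <- sum(Cinv * Ps[[i]])
      t2 <- as.numeric(crossprod(CiY, Ps[[i]] %*% CiY))
      gamma[i] <- max(gamma[i] - gamma[i]^2 / ranks[i] * (t1 - t2), 0)
    }
    # numerical floor on the sensor-noise level keeps C invertible when a
    # noiseless topography drives all hyperparameters toward zero
    gamma[1] <- max(gamma[1], y2 / e * 1e-10)
  }
  # posterior mean Phi = C2 X' Cinv Y
  w <- as.numeric(Cinv %*% Y)
  phi <- numeric(ncol(X))
  Xtw <- as.numeric(crossprod(X, w))
  for (i in seq_len(m)) {
    pr <- proj[[i]]$prior
    g <- gamma[i + 1]
    if (g == 0) next
    phi <- phi + if (!is.null(pr$diag)) g * pr$diag * Xtw
                 else g * as.numeric(pr$factor %*% crossprod(pr$factor, Xtw))
  }
  gamma <- setNames(gamma, c("noise",
                             vapply(proj, function(p) p$prior$label, "")))
  structure(list(gamma = gamma, free_energy = Fs, posterior_mean = phi,
                 converged = converged, trace_P = traces[-1], proj = proj),
            class = "reml_result")
}

#' @export
print.reml_result <- function(x, ...) {
  cat("<reml_result> ", length(x$gamma) - 1, " source prior(s), ",
      length(x$free_energy), " iteration(s), converged: ", x$converged,
      "\n", sep = "")
  invisible(x)
}

#' Project priors once for repeated inversions
#'
#' Precomputes the sensor-space covariance components `X Q_i X'` so several
#' topographies can be inverted against the same prior set without repeating
#' the projection.
#'
#' @inheritParams reml_invert
#' @return The projected prior list accepted by [reml_invert()].
#' @export
project_priors <- function(priors, X) {
  if (inherits(X, "leadfield")) X <- X$gain
  out <- .project_priors(priors, X)
  attr(out, "projected") <- TRUE
  out
}

#' Match EEG components to fMRI networks by hyperparameter profile
#'
#' Per EEG component the normalized contribution of prior i is
#' `rho_i = g_i tr(X Q_i X') / sum_j g_j tr(X Q_j X')` (sensor noise
#' excluded). The argmax prior wins; when MSP wins (ties break toward MSP,
#' the conservative call) the component is EEG-specific. fMRI components
#' matched by no EEG component are fMRI-specific.
#'
#' @param results list of [reml_invert()] results, one per EEG component,
#'   all computed against the same prior list.
#' @param n_fmri total number of fMRI components (defaults to the number of
#'   fMRI priors in the first result).
#' @return An object of class `match_table`: `contributions` (EEG x priors
#'   matrix of rho), `match` (fMRI component index per EEG component, NA for
#'   EEG-specific), `common` (two-column matrix eeg/fmri), `eeg_specific`,
#'   `fmri_specific`.
#' @export
match_networks <- function(results, n_fmri = NULL) {
  if (length(results) == 0) stop("empty result list")
  labels <- names(results[[1]]$gamma)[-1]
  types <- vapply(results[[1]]$proj, function(p) p$prior$type, "")
  fmri_idx <- vapply(results[[1]]$proj, function(p) p$prior$index, 1L)
  if (is.null(n_fmri)) n_fmri <- sum(types == "fmri")
  contrib <- t(vapply(results, function(r) {
    if (!identical(names(r$gamma)[-1], labels))
      stop("all results must share the same prior list")
    raw <- r$gamma[-1] * r$trace_P
    tot <- sum(raw)
    if (tot == 0) rep(0, length(raw)) else raw / tot
  }, numeric(length(labels))))
  colnames(contrib) <- labels
  match <- integer(nrow(contrib))
  for (i in seq_len(nrow(contrib))) {
    best <- which(contrib[i, ] == max(contrib[i, ]))
    if (any(types[best] == "msp") || max(contrib[i, ]) == 0) {
      match[i] <- NA_integer_            # MSP wins or degenerate: EEG-specific
    } else {
      match[i] <- fmri_idx[best[1]]
    }
  }
  common <- cbind(eeg = which(!is.na(match)),
                  fmri = match[!is.na(match)])
  structure(list(contributions = contrib, match = match,
                 common = common,
                 eeg_specific = which(is.na(match)),
                 fmri_specific = setdiff(seq_len(n_fmri), match),
                 n_fmri = n_fmri),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  for (i in seq_along(x$match))
    cat("  EEG ", i, " -> ",
        if (is.na(x$match[i])) "EEG-specific (MSP)"
        else paste0("fMRI ", x$match[i]), "\n", sep = "")
  cat("  fMRI-specific:",
      if (length(x$fmri_specific)) paste(x$fmri_specific, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @describeIn match_networks tidy contribution table: one row per EEG
#'   component and prior.
#' @param x a `match_table`.
#' @param ... unused.
#' @export
tidy.match_table <- function(x, ...) {
  tibble::tibble(
    eeg = rep(seq_len(nrow(x$contributions)), ncol(x$contributions)),
    prior = rep(colnames(x$contributions), each = nrow(x$contributions)),
    contribution = as.numeric(x$contributions),
    matched = rep(x$match, ncol(x$contributions)))
}

#' Threshold a posterior source map
#'
#' Retains the dipoles whose posterior magnitude lies in the top `quantile`
#' fraction of `|Phi|` (the display convention for sparse source maps);
#' at least `ceiling(quantile * d)` dipoles are kept, ties resolved in
#' deterministic index order.
#'
#' @param result a [reml_invert()] result (or numeric vector of source
#'   amplitudes).
#' @param quantile fraction retained (default 0.01).
#' @return List with `support` (dipole indices) and `values` (amplitudes on
#'   the support).
#' @export
source_map <- function(result, quantile = 0.01) {
  phi <- if (inherits(result, "reml_result")) result$posterior_mean
         else as.numeric(result)
  stopifnot(quantile > 0, quantile <= 1)
  d <- length(phi)
  nkeep <- min(d, ceiling(quantile * d))
  ord <- order(-abs(phi), seq_len(d))
  support <- sort(ord[seq_len(nkeep)])
  list(support = support, values = phi[support])
}
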