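#' Spatial independent component analysis
#'
#' Fixed-point (FastICA, tanh contrast) decomposition arranged so that
#' statistical independence is imposed across spatial locations: the input
#' `locations x times` matrix is transposed, each time point is treated as a
#' mixture of spatial patterns, and the extracted components are spatial maps
#' with the mixing matrix holding their time courses.
#'
#' In `"deflation"` mode units are extracted one at a time and extraction
#' stops at the first unit that fails to converge within `max_iter`
#' iterations — on data with a few strong non-Gaussian spatial patterns on a
#' Gaussian background the iteration typically stalls right after the real
#' patterns have been extracted, which bounds the component count
#' data-adaptively. `"symmetric"` mode estimates exactly `n_max` units
#' jointly.
#'
#' @param data locations x times matrix (channels x time for EEG, voxels x
#'   volumes for fMRI).
#' @param n_max maximum number of components; defaults to the rank of the
#'   whitened problem, i.e. the number of channels (EEG) or time points
#'   (fMRI), whichever is the smaller dimension.
#' @param mode `"deflation"` (default) or `"symmetric"`.
#' @param seed seed for the random initial unmixing vectors.
#' @param max_iter fixed-point iterations per unit (default 200).
#' @param tol convergence tolerance on the direction change (default 1e-4).
#' @param whitening optional precomputed whitening from [ica_whiten()]
#'   (deterministic, so it can be shared across restarts).
#' @param independence `"space"` (default): independence across locations,
#'   time points are the mixtures — the fMRI convention. `"time"`:
#'   independence across time, channels are the mixtures — the EEG
#'   convention, where the trial-wise variance structure of the courses
#'   carries the identifiable non-Gaussianity. Either way the result holds
#'   spatial maps and time courses in the same slots.
#' @param n_reduce optionally reduce to this many dominant principal
#'   components before ICA (standard practice when a few strong patterns sit
#'   on a high-dimensional noise floor).
#' @return An object of class `component_set`: `spatial_maps`
#'   (n_comp x locations, unit-norm rows, largest-magnitude entry positive),
#'   `time_courses` (n_comp x times, least-squares mixing courses),
#'   `modality` label and `provenance`.
#' @export
spatial_ica <- function(data, n_max = NULL, mode = c("deflation", "symmetric"),
                        seed = 1, max_iter = 200, tol = 1e-4,
                        whitening = NULL,
                        independence = c("space", "time"),
                        n_reduce = NULL) {
  mode <- match.arg(mode)
  independence <- match.arg(independence)
  if (!all(is.finite(data))) stop("data must be finite")
  if (is.null(whitening))
    whitening <- ica_whiten(data, independence = independence,
                            n_reduce = n_reduce)
  Z <- whitening$Z                      # r x locations, unit covariance
  r <- nrow(Z); nloc <- ncol(Z)
  if (is.null(n_max)) n_max <- r
  if (n_max > r) {
    warning("rank-deficient data: reducing n_max from ", n_max, " to ", r)
    n_max <- r
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- matrix(0, 0, r)
  if (mode == "deflation") {
    for (i in seq_len(n_max)) {
      w <- rnorm(r); w <- w / sqrt(sum(w^2))
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        u <- as.numeric(w %*% Z)
        g <- tanh(u)
        wn <- as.numeric(Z %*% g) / nloc - mean(1 - g^2) * w
        if (nrow(W) > 0) wn <- wn - as.numeric(crossprod(W, W %*% wn))
        nrm <- sqrt(sum(wn^2))
        if (nrm < 1e-12) break
        wn <- wn / nrm
        # classic FastICA stopping rule: direction change below tol
        # (up to sign); Gaussian directions keep wandering and fail this
        if (min(sum((wn - w)^2), sum((wn + w)^2)) < tol^2) {
          w <- wn; converged <- TRUE; break
        }
        w <- wn
      }
      if (!converged) break             # deflation stall: stop extracting
      W <- rbind(W, w)
    }
    if (nrow(W) == 0)
      stop("decomposition failed: no unit converged")
  } else {
    W <- matrix(rnorm(n_max * r), n_max, r)
    W <- .sym_decorrelate(W)
    for (it in seq_len(max_iter)) {
      U <- W %*% Z
      G <- tanh(U)
      Wn <- G %*% t(Z) / nloc - diag(rowMeans(1 - G^2), n_max) %*% W
      Wn <- .sym_decorrelate(Wn)
      # |cos| near 1 within tol^2/2 is the same angle criterion as the
      # deflation rule ||w_new -/+ w_old|| < tol
      delta <- max(abs(abs(rowSums(Wn * W)) - 1))
      W <- Wn
      if (delta < tol^2 / 2) break
    }
    if (delta >= tol^2 / 2)
      warning("symmetric FastICA did not fully converge (delta = ",
              signif(delta, 3), ")")
  }

  comps <- W %*% Z                       # n_comp x samples
  .finish_component_set(comps, data, provenance = list(
    seed = seed, mode = mode, n_extracted = nrow(W),
    independence = whitening$independence))
}

# PCA whitening via the economical SVD of the mixtures x samples matrix
#' Whitening for [spatial_ica()]
#'
#' @param data locations x times matrix.
#' @param rank_tol relative singular-value cutoff (default 1e-10).
#' @param independence `"space"` (mixtures = time points, samples =
#'   locations) or `"time"` (mixtures = channels, samples = time points).
#' @param n_reduce keep only this many dominant components (default: full
#'   numerical rank). `"auto"` keeps the components whose variance exceeds
#'   twice the median eigenvalue — the median estimates the noise floor, so
#'   this retains the patterns standing clearly above it (at least 2).
#' @return List with whitened samples `Z` (rank x samples), the retained
#'   `rank` and the arrangement; deterministic, reusable across ICA
#'   restarts.
#' @export
ica_whiten <- function(data, rank_tol = 1e-10,
                       independence = c("space", "time"), n_reduce = NULL) {
  independence <- match.arg(independence)
  M <- if (independence == "space") t(data) else data
  M <- M - rowMeans(M)
  sv <- svd(M, nu = 0)
  r <- sum(sv$d > rank_tol * sv$d[1])
  if (identical(n_reduce, "auto")) {
    # keep the dimensions standing clearly above the noise floor; the median
    # over the FULL spectrum estimates that floor (and is ~0 for exactly
    # low-rank data, which then keeps every structural dimension)
    ev <- sv$d^2
    r <- min(r, max(2L, sum(ev > 2 * stats::median(ev))))
  } else if (!is.null(n_reduce)) r <- min(r, n_reduce)
  Z <- sqrt(ncol(M)) * t(sv$v[, seq_len(r), drop = FALSE])
  list(Z = Z, rank = r, independence = independence)
}

.sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

# unit-norm + sign convention on the maps, least-squares fit of the other
# factor against the data; `comps` are the independent components over the
# sample dimension of the chosen arrangement
.finish_component_set <- function(comps, data, provenance,
                                  modality = NA_character_) {
  if (identical(provenance$independence, "time")) {
    # comps are time courses; spatial maps (mixing columns) by LS
    Dc <- data - rowMeans(data)
    G <- comps %*% t(comps)
    A <- t(tryCatch(solve(G, comps %*% t(Dc)),
                    error = function(e)
                      solve(G + diag(1e-8 * mean(diag(G)), nrow(G)),
                            comps %*% t(Dc))))           # locations x n
    nrm <- sqrt(colSums(A^2)); nrm[nrm == 0] <- 1
    maps <- t(A) / nrm
    sgn <- apply(maps, 1, function(m) sign(m[which.max(abs(m))]))
    sgn[sgn == 0] <- 1
    maps <- maps * sgn
    tc <- comps * (sgn * nrm)
  } else {
    maps <- .normalize_maps(comps)
    tc <- .refit_time_courses(maps, data)
  }
  structure(list(spatial_maps = maps, time_courses = tc,
                 modality = modality, provenance = provenance),
            class = "component_set")
}

.normalize_maps <- function(maps) {
  nrm <- sqrt(rowSums(maps^2))
  nrm[nrm == 0] <- 1
  maps <- maps / nrm
  sgn <- apply(maps, 1, function(m) sign(m[which.max(abs(m))]))
  sgn[sgn == 0] <- 1
  maps * sgn
}

.refit_time_courses <- function(maps, data) {
  Dc <- sweep(data, 2, colMeans(data))   # remove per-time mean over locations
  G <- maps %*% t(maps)
  rhs <- maps %*% Dc
  tryCatch(solve(G, rhs),
           error = function(e)            # ridge fallback for collinear maps
             solve(G + diag(1e-8 * mean(diag(G)), nrow(G)), rhs))
}

#' @export
print.component_set <- function(x, ...) {
  cat("<component_set> ", nrow(x$spatial_maps), " components over ",
      ncol(x$spatial_maps), " locations x ", ncol(x$time_courses),
      " time points", if (!is.na(x$modality)) paste0(" (", x$modality, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Consensus components across ICA restarts
#'
#' Pools the spatial maps of several [spatial_ica()] runs, clusters them by
#' absolute spatial correlation (average-linkage agglomerative clustering cut
#' at `1 - similarity_threshold`), keeps clusters that recur in at least
#' `min_occurrence` of the runs, and returns one centroid per surviving
#' cluster: the sign-aligned mean map, re-normalized, with its time course
#' refit by least squares against `data` when supplied.
#'
#' @param runs list of `component_set` objects with a common location
#'   dimension.
#' @param data optional locations x times matrix for the time-course refit.
#' @param similarity_threshold absolute-correlation threshold defining a
#'   cluster (default 0.8).
#' @param min_occurrence minimum fraction of runs a cluster must appear in
#'   (default 0.5).
#' @return A `component_set` of cluster centroids, ordered by cluster size
#'   (provenance records sizes and run counts). Empty (with a warning) when
#'   no cluster recurs often enough.
#' @export
consensus_components <- function(runs, data = NULL,
                                 similarity_threshold = 0.8,
                                 min_occurrence = 0.5) {
  stopifnot(length(runs) >= 2)
  nloc <- ncol(runs[[1]]$spatial_maps)
  if (!all(vapply(runs, function(r) ncol(r$spatial_maps), 1L) == nloc))
    stop("runs must share the location dimension")
  maps <- do.call(rbind, lapply(runs, `[[`, "spatial_maps"))
  run_id <- rep(seq_along(runs),
                vapply(runs, function(r) nrow(r$spatial_maps), 1L))
  if (nrow(maps) < 2) stop("need at least two pooled components")

  co <- abs(stats::cor(t(maps)))
  co[!is.finite(co)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  cl <- stats::cutree(hc, h = 1 - similarity_threshold)

  tcs <- do.call(rbind, lapply(runs, `[[`, "time_courses"))
  keep <- list(); reps <- list(); sizes <- integer(0); nruns <- integer(0)
  for (g in unique(cl)) {
    members <- which(cl == g)
    n_run <- length(unique(run_id[members]))
    if (n_run / length(runs) < min_occurrence) next
    ref <- maps[members[1], ]
    aligned <- t(vapply(members, function(i) {
      s <- sign(sum(maps[i, ] * ref)); if (s == 0) s <- 1
      s * maps[i, ]
    }, numeric(nloc)))
    keep[[length(keep) + 1]] <- colMeans(aligned)
    reps[[length(reps) + 1]] <- tcs[members[1], ]
    sizes <- c(sizes, length(members))
    nruns <- c(nruns, n_run)
  }
  if (length(keep) == 0) {
    warning("no component cluster reached min_occurrence; returning an ",
            "empty set")
    maps0 <- matrix(0, 0, nloc)
    tc0 <- matrix(0, 0, if (is.null(data)) ncol(runs[[1]]$time_courses)
                        else ncol(data))
    return(structure(list(spatial_maps = maps0, time_courses = tc0,
                          modality = runs[[1]]$modality,
                          provenance = list(cluster_sizes = integer(0))),
                     class = "component_set"))
  }
  ord <- order(-sizes, seq_along(sizes))
  keep <- keep[ord]; reps <- reps[ord]; sizes <- sizes[ord]; nruns <- nruns[ord]
  # merge centroids that ended up near-identical despite the tree cut
  # (degenerate decompositions can duplicate a pattern across clusters)
  drop <- logical(length(keep))
  for (i in seq_along(keep)) {
    if (drop[i]) next
    for (j in seq_along(keep)) {
      if (j <= i || drop[j]) next
      if (abs(stats::cor(keep[[i]], keep[[j]])) > similarity_threshold)
        drop[j] <- TRUE
    }
  }
  keep <- keep[!drop]; reps <- reps[!drop]
  sizes <- sizes[!drop]; nruns <- nruns[!drop]
  ord <- seq_along(keep)
  cent <- .normalize_maps(do.call(rbind, keep))
  prov <- list(cluster_sizes = sizes, cluster_runs = nruns,
               n_runs = length(runs))
  if (!is.null(data)) {
    .finish_component_set(cent, data, prov, modality = runs[[1]]$modality)
  } else {
    raw <- do.call(rbind, keep)[ord, , drop = FALSE]
    flip <- sign(rowSums(cent * raw)); flip[flip == 0] <- 1
    tc <- do.call(rbind, reps)[ord, , drop = FALSE] * flip
    structure(list(spatial_maps = cent, time_courses = tc,
                   modality = runs[[1]]$modality, provenance = prov),
              class = "component_set")
  }
}

#' Retain a subset of components
#'
#' Drops user-identified artifact components by index (manual screening; the
#' judgement itself is up to the analyst).
#'
#' @param set a `component_set`.
#' @param exclude integer indices to drop (1-based); empty keeps everything.
#' @return The screened `component_set` with updated provenance.
#' @export
screen_components <- function(set, exclude = integer(0)) {
  n <- nrow(set$spatial_maps)
  exclude <- as.integer(exclude)
  if (length(exclude) > 0 && (any(exclude < 1) || any(exclude > n)))
    stop("exclude indices out of range 1..", n)
  keep <- setdiff(seq_len(n), exclude)
  set$spatial_maps <- set$spatial_maps[keep, , drop = FALSE]
  set$time_courses <- set$time_courses[keep, , drop = FALSE]
  set$provenance$screened_out <- exclude
  set
}

#' Z-score a spatial map and report activated locations
#'
#' fMRI convention: map intensities are transformed to z scores and locations
#' with |z| above the threshold are flagged as activated.
#'
#' @param map numeric vector (one spatial map).
#' @param z_threshold default 3.
#' @return List with `z` (the z-scored map) and `active` (indices).
#' @export
map_activation <- function(map, z_threshold = 3) {
  z <- .znorm(map)
  list(z = z, active = which(abs(z) > z_threshold))
}
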