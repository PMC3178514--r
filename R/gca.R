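#' @name gca
#' @title Vector autoregression and conditional Granger causality
#'
#' @description
#' The network time courses are modeled as a VAR(p) process
#' `S(t) = sum_m A_m S(t-m) + E(t)`. Single long series are fit by the
#' Levinson-Wiggins-Robinson (multichannel Levinson) recursion on the sample
#' autocovariance sequence; trial data are fit by pooled least squares with a
#' lag-trimmed design stacked across trials, each trial treated as an
#' independent realization of one stationary process. The model order is
#' selected by the multivariate BIC, directed influences are quantified by
#' the conditional (Geweke) Granger measure
#' `F_{j->i} = ln(Sigma_restricted[i,i] / Sigma_full[i,i])`, and edge
#' significance is a block F-test on all p lag coefficients of the candidate
#' source, Bonferroni-corrected over the n(n-1) ordered pairs.
NULL

# normalize data to a list of k x len trial matrices, demeaned per trial
.as_trials <- function(data, demean = TRUE) {
  tr <- if (is.list(data)) data else list(data)
  tr <- lapply(tr, function(x) {
    x <- as.matrix(x)
    if (demean) x - rowMeans(x) else x
  })
  k <- nrow(tr[[1]])
  if (!all(vapply(tr, nrow, 1L) == k)) stop("trials must share channel count")
  tr
}

# lag-trimmed stacked regression arrays: Y (k x N), X (k*p x N)
# predictor rows ordered channel-fastest within lag: (lag1 ch1..chk, lag2 ...)
.stack_lags <- function(trials, p) {
  Ys <- list(); Xs <- list()
  for (tr in trials) {
    len <- ncol(tr)
    if (len <= p) stop("trial length ", len, " too short for order ", p)
    idx <- (p + 1):len
    Ys[[length(Ys) + 1]] <- tr[, idx, drop = FALSE]
    Xs[[length(Xs) + 1]] <- do.call(rbind, lapply(seq_len(p), function(m)
      tr[, idx - m, drop = FALSE]))
  }
  list(Y = do.call(cbind, Ys), X = do.call(cbind, Xs))
}

# pooled OLS fit; rows = subset of predictor rows to use (restricted models)
.ols_fit <- function(Y, X, rows = seq_len(nrow(X))) {
  Xr <- X[rows, , drop = FALSE]
  XtX <- tcrossprod(Xr)
  cf <- tryCatch(t(solve(XtX, Xr %*% t(Y))),
                 error = function(e) stop("singular regression design: ",
                                          conditionMessage(e)))
  resid <- Y - cf %*% Xr
  list(coef = cf, rss = rowSums(resid^2),
       sigma = tcrossprod(resid) / ncol(Y))
}

#' Fit a VAR model
#'
#' @param data a k x T matrix (single series) or a list of k x len trial
#'   matrices. Channels are demeaned per trial by default.
#' @param p model order (>= 1).
#' @param method `"auto"` (LWR for a single series, pooled OLS for trials),
#'   `"lwr"` or `"ols"`.
#' @param demean remove per-trial channel means before fitting (default
#'   TRUE).
#' @return An object of class `var_model`: `order`, `coefficients`
#'   (k x k x p), `noise_cov` (ML innovation covariance), `n_effective`,
#'   `fit_mode`.
#' @export
fit_var <- function(data, p, method = c("auto", "lwr", "ols"),
                    demean = TRUE) {
  method <- match.arg(method)
  stopifnot(p >= 1)
  trials <- .as_trials(data, demean)
  if (method == "auto")
    method <- if (length(trials) == 1) "lwr" else "ols"
  k <- nrow(trials[[1]])
  if (method == "lwr") {
    if (length(trials) != 1)
      stop("LWR fitting applies to a single series; use method = 'ols' for trials")
    x <- trials[[1]]
    Tt <- ncol(x)
    C <- lapply(0:p, function(j)
      tcrossprod(x[, (1 + j):Tt, drop = FALSE],
                 x[, 1:(Tt - j), drop = FALSE]) / Tt)
    fit <- .lwr(C, p)
    A <- fit$A; Sigma <- fit$sigma; neff <- Tt - p
  } else {
    sl <- .stack_lags(trials, p)
    fit <- .ols_fit(sl$Y, sl$X)
    neff <- ncol(sl$Y)
    A <- array(fit$coef, c(k, k * p))
    dim(A) <- c(k, k, p)
    Sigma <- fit$sigma
  }
  structure(list(order = p, coefficients = A, noise_cov = Sigma,
                 n_effective = neff, fit_mode = method, k = k),
            class = "var_model")
}

# Whittle's multichannel Levinson (LWR) recursion on autocovariances
# C[[m+1]] = C_m = E[x_t x_{t-m}^T]; returns forward coefficients and the
# forward prediction-error covariance.
.lwr <- function(C, p) {
  k <- nrow(C[[1]])
  V <- C[[1]]; W <- C[[1]]               # forward / backward error cov
  A <- list(); B <- list()
  for (m in seq_len(p)) {
    Delta <- C[[m + 1]]
    if (m > 1)
      for (i in seq_len(m - 1)) Delta <- Delta - A[[i]] %*% C[[m - i + 1]]
    K  <- Delta %*% solve(W)
    Kb <- t(Delta) %*% solve(V)
    An <- vector("list", m); Bn <- vector("list", m)
    An[[m]] <- K; Bn[[m]] <- Kb
    if (m > 1)
      for (i in seq_len(m - 1)) {
        An[[i]] <- A[[i]] - K %*% B[[m - i]]
        Bn[[i]] <- B[[i]] - Kb %*% A[[m - i]]
      }
    V <- V - K %*% t(Delta)
    W <- W - Kb %*% Delta
    A <- An; B <- Bn
  }
  arr <- array(0, c(k, k, p))
  for (m in seq_len(p)) arr[, , m] <- A[[m]]
  list(A = arr, sigma = (V + t(V)) / 2)
}

#' Select the VAR order by BIC
#'
#' `BIC(p) = ln det Sigma(p) + k^2 p ln(N_eff) / N_eff`, with `Sigma(p)` the
#' ML innovation covariance and `N_eff` the lag-trimmed sample count summed
#' over trials; the smallest order attaining the minimum over `1..p_max`
#' wins.
#'
#' @inheritParams fit_var
#' @param p_max largest order searched (default 10).
#' @return The selected order (integer). The BIC curve is attached as
#'   attribute `"bic"`.
#' @export
select_order_bic <- function(data, p_max = 10, method = c("auto", "lwr", "ols"),
                             demean = TRUE) {
  method <- match.arg(method)
  trials <- .as_trials(data, demean)
  k <- nrow(trials[[1]])
  min_len <- min(vapply(trials, ncol, 1L))
  if (min_len <= p_max)
    p_max <- min_len - 1
  neff_at <- function(p) sum(vapply(trials, ncol, 1L) - p)
  if (p_max < 1 || neff_at(p_max) <= k * p_max + 1)
    stop("insufficient samples: need trial lengths > ", k * p_max + 1,
         " effective samples for p_max = ", p_max)
  bic <- vapply(seq_len(p_max), function(p) {
    fit <- fit_var(trials, p, method = method, demean = FALSE)
    n <- fit$n_effective
    d <- determinant(fit$noise_cov, logarithm = TRUE)
    as.numeric(d$modulus) + k^2 * p * log(n) / n
  }, numeric(1))
  p_sel <- which.min(bic)
  attr(p_sel, "bic") <- bic
  p_sel
}

#' Conditional Granger causality magnitudes
#'
#' Geweke's conditional measure: for each ordered pair (j -> i) the full
#' model regresses every channel on p lags of all channels, the restricted
#' model omits channel j's lags, and
#' `F_{j->i} = ln(Sigma_restricted[i,i] / Sigma_full[i,i])` (ML residual
#' variances). Nonnegative up to estimation noise; the diagonal is `NA`.
#'
#' @inheritParams fit_var
#' @param p model order.
#' @return A k x k matrix of magnitudes (`[i, j]` holds j -> i).
#' @export
gc_magnitude <- function(data, p, demean = TRUE) {
  gc_edges(data, p, demean = demean)$magnitudes
}

#' Granger-causal edges with Bonferroni-corrected F-tests
#'
#' For each ordered pair (j -> i) a block F-test compares the full regression
#' for target i against the regression with channel j's p lags removed:
#' `F = ((RSS_r - RSS_f)/p) / (RSS_f/(N_eff - k p - 1))` on
#' `(p, N_eff - k p - 1)` degrees of freedom. Edges are declared where the
#' p-value is below `alpha_nominal / (n (n - 1))` (self-influences excluded
#' from testing and from the correction count).
#'
#' @inheritParams fit_var
#' @param p model order.
#' @param alpha_nominal nominal familywise level (default 0.01).
#' @return An object of class `gc_graph`: `magnitudes`, `p_values`,
#'   `adjacency` (logical, `[i, j]` TRUE when j -> i is significant, stored
#'   with `from = j` as the column), `alpha_nominal`, `threshold`, `n_nodes`,
#'   `order`.
#' @export
gc_edges <- function(data, p, alpha_nominal = 0.01, demean = TRUE) {
  trials <- .as_trials(data, demean)
  k <- nrow(trials[[1]])
  sl <- .stack_lags(trials, p)
  neff <- ncol(sl$Y)
  df2 <- neff - k * p - 1
  if (df2 <= 0) stop("nonpositive residual degrees of freedom (", df2, ")")
  full <- .ols_fit(sl$Y, sl$X)
  mags <- matrix(NA_real_, k, k)
  pv <- matrix(NA_real_, k, k)
  Fs <- matrix(NA_real_, k, k)
  lag_rows <- function(j) j + k * (seq_len(p) - 1)
  for (j in seq_len(k)) {
    restr <- .ols_fit(sl$Y, sl$X, rows = setdiff(seq_len(k * p), lag_rows(j)))
    for (i in seq_len(k)) {
      if (i == j) next
      mags[i, j] <- log(restr$rss[i] / full$rss[i])
      Fstat <- ((restr$rss[i] - full$rss[i]) / p) / (full$rss[i] / df2)
      Fs[i, j] <- max(Fstat, 0)
      pv[i, j] <- pf(max(Fstat, 0), p, df2, lower.tail = FALSE)
    }
  }
  thr <- alpha_nominal / (k * (k - 1))
  adj <- !is.na(pv) & pv < thr
  structure(list(magnitudes = mags, p_values = pv, f_statistics = Fs,
                 adjacency = adj, alpha_nominal = alpha_nominal,
                 threshold = thr, n_nodes = k, order = p,
                 n_effective = neff),
            class = "gc_graph")
}

#' @export
print.gc_graph <- function(x, ...) {
  cat("<gc_graph> ", x$n_nodes, " nodes, order ", x$order, ", ",
      sum(x$adjacency), " significant edge(s) at per-edge threshold ",
      signif(x$threshold, 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn gc_edges tidy the edge table: one row per ordered pair with
#'   magnitude, F statistic, p-value and significance flag.
#' @param x a `gc_graph`.
#' @param ... unused.
#' @export
tidy.gc_graph <- function(x, ...) {
  k <- x$n_nodes
  idx <- which(row(x$magnitudes) != col(x$magnitudes), arr.ind = TRUE)
  tibble::tibble(
    from = idx[, 2], to = idx[, 1],
    magnitude = x$magnitudes[idx],
    statistic = x$f_statistics[idx],
    p_value = x$p_values[idx],
    significant = x$adjacency[idx])
}

#' @describeIn gc_edges one-row summary: nodes, order, edge count,
#'   causal density.
#' @export
glance.gc_graph <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes, order = x$order,
                 n_edges = sum(x$adjacency),
                 density = sum(x$adjacency) / (x$n_nodes * (x$n_nodes - 1)),
                 threshold = x$threshold)
}
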