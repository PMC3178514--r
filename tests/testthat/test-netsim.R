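# independent oracle: stationary covariance of the companion form by
# solving the discrete Lyapunov equation vec(P) = (I - F (x) F)^-1 vec(Q)
companion_moments <- function(spec) {
  k <- spec$k; p <- spec$p
  F <- matrix(0, k * p, k * p)
  for (m in seq_len(p)) F[seq_len(k), (m - 1) * k + seq_len(k)] <- spec$A[, , m]
  if (p > 1) F[k + seq_len(k * (p - 1)), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  Q <- matrix(0, k * p, k * p)
  Q[seq_len(k), seq_len(k)] <- spec$sigma
  P <- matrix(solve(diag((k * p)^2) - kronecker(F, F), as.numeric(Q)), k * p)
  list(P = P, lag1 = F %*% P)
}

test_that("default graph spec encodes the benchmark network", {
  s <- default_graph_spec(0.5)
  expect_equal(s$k, 4)
  expect_equal(s$p, 2)
  e <- edge_set(s)
  expect_equal(e, cbind(from = c(1L, 2L, 3L, 3L), to = c(3L, 3L, 2L, 4L)),
               ignore_attr = TRUE)
  # no coupling: empty edge set, four independent oscillators
  expect_equal(nrow(edge_set(default_graph_spec(0))), 0)
  # alternative direction for the fMRI-only edge
  e2 <- edge_set(default_graph_spec(0.5, s4_direction = "S4->S1"))
  expect_true(any(e2[, 1] == 4 & e2[, 2] == 1))
  expect_error(default_graph_spec(0.9), "0, 0.7")
})

test_that("spectral radius matches scalar cases and stays subcritical", {
  a1 <- causal_graph_spec(1, array(0.6, c(1, 1, 1)))
  expect_equal(spectral_radius(a1), 0.6)
  a0 <- causal_graph_spec(2, array(0, c(2, 2, 1)))
  expect_equal(spectral_radius(a0), 0)
  rhos <- vapply(c(0, 0.1, 0.3, 0.5, 0.7),
                 function(cc) spectral_radius(default_graph_spec(cc)), 1)
  expect_true(all(rhos < 1))
  expect_true(all(diff(rhos) > 0))       # monotone in coupling
  # cross-check against an independently assembled companion matrix
  s <- default_graph_spec(0.5)
  F <- matrix(0, 8, 8)
  for (m in 1:2) F[1:4, (m - 1) * 4 + 1:4] <- s$A[, , m]
  F[5:8, 1:4] <- diag(4)
  expect_equal(spectral_radius(s), max(Mod(eigen(F)$values)),
               tolerance = 1e-10)
})

test_that("unstable specifications are refused", {
  A <- array(1.2, c(1, 1, 1))
  expect_error(causal_graph_spec(1, A), "unstable")
  s <- causal_graph_spec(1, A, check_stability = FALSE)
  expect_error(simulate_sources(s, 100), "refusing")
})

test_that("simulation is seed-deterministic with the requested shape", {
  s <- default_graph_spec(0.5)
  a <- simulate_sources(s, n_samples = 500, burn_in = 100, seed = 7)
  b <- simulate_sources(s, n_samples = 500, burn_in = 100, seed = 7)
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values), c(4L, 500L))
  expect_false(identical(
    a$values, simulate_sources(s, n_samples = 500, burn_in = 100,
                               seed = 8)$values))
  expect_true(all(is.finite(a$values)))
})

test_that("uncoupled channels decorrelate and long runs are stationary", {
  s0 <- default_graph_spec(0)
  x <- simulate_sources(s0, n_samples = 20000, seed = 3)$values
  co <- cor(t(x))
  expect_lt(max(abs(co[upper.tri(co)])), 0.05)
  # variance of the two halves agrees within 10% at the default spec
  x5 <- simulate_sources(default_graph_spec(0.5), seed = 11)$values
  v1 <- apply(x5[, 1:9000], 1, var)
  v2 <- apply(x5[, 9001:18000], 1, var)
  expect_true(all(abs(v2 / v1 - 1) < 0.10))
})

test_that("lagged cross-covariance matches the Yule-Walker solution", {
  s <- default_graph_spec(0.7)
  mom <- companion_moments(s)
  x <- simulate_sources(s, n_samples = 200000, seed = 5)$values
  Tt <- ncol(x)
  emp <- sum(x[3, 2:Tt] * x[1, 1:(Tt - 1)]) / (Tt - 1)
  expect_equal(emp, mom$lag1[3, 1], tolerance = 0.05)
  # and the stationary variances
  empv <- apply(x, 1, function(r) mean(r^2))
  expect_equal(empv, diag(mom$P)[1:4], tolerance = 0.05, ignore_attr = TRUE)
})

test_that("Gaussian innovations remain available and differ from Laplace", {
  s <- default_graph_spec(0.3)
  g <- simulate_sources(s, n_samples = 30000, seed = 2,
                        innovations = "gaussian")$values
  l <- simulate_sources(s, n_samples = 30000, seed = 2,
                        innovations = "laplace")$values
  kg <- mean(scale(g[1, ])^4) - 3
  kl <- mean(scale(l[1, ])^4) - 3
  expect_lt(abs(kg), 0.15)
  expect_gt(kl, 0.3)
})

test_that("ground-truth edges are recoverable from raw sources", {
  # strong coupling, full-length series: Bonferroni-corrected conditional
  # GC recovers exactly the true edge set in nearly every run
  hits <- 0; n <- 32
  for (r in seq_len(n)) {
    x <- simulate_sources(default_graph_spec(0.7), seed = 1000 + r)$values
    g <- gc_edges(x, 2)
    want <- matrix(FALSE, 4, 4)
    want[3, 1] <- want[3, 2] <- want[2, 3] <- want[4, 3] <- TRUE
    hits <- hits + identical(g$adjacency, want)
  }
  expect_gte(hits / n, 0.95)
})
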