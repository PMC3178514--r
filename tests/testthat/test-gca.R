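simulate_var <- function(A, Tt, seed, sigma = diag(nrow(A))) {
  k <- nrow(A)
  spec <- causal_graph_spec(k, array(A, c(k, k, 1)), sigma = sigma)
  simulate_sources(spec, n_samples = Tt, burn_in = 200, seed = seed,
                   innovations = "gaussian")$values
}

test_that("VAR(1) coefficients are recovered consistently", {
  A <- rbind(c(0.5, 0.2), c(-0.3, 0.4))
  x <- simulate_var(A, 1e5, seed = 1)
  f <- fit_var(x, 1, method = "ols")
  expect_equal(f$coefficients[, , 1], A, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(f$noise_cov, diag(2), tolerance = 0.05, ignore_attr = TRUE)
  f2 <- fit_var(x, 1, method = "lwr")
  expect_equal(f2$coefficients[, , 1], A, tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("fitting order 1 to white noise shrinks the coefficients", {
  set.seed(2)
  x <- matrix(rnorm(3 * 20000), 3)
  f <- fit_var(x, 1, method = "ols")
  expect_lt(max(abs(f$coefficients)), 0.03)
  expect_equal(f$noise_cov, diag(3), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("LWR and pooled OLS agree on a long single series", {
  x <- simulate_sources(default_graph_spec(0.5), seed = 3)$values  # T = 18000
  fl <- fit_var(x, 2, method = "lwr")
  fo <- fit_var(x, 2, method = "ols")
  expect_lt(max(abs(fl$coefficients - fo$coefficients)), 1e-3)
  expect_lt(max(abs(fl$noise_cov - fo$noise_cov)), 1e-3)
  # LWR internal recursion agrees with a direct block-Toeplitz Yule-Walker
  # solve of the same sample autocovariances
  k <- 4; p <- 2; Tt <- ncol(x)
  xc <- x - rowMeans(x)
  C <- lapply(0:p, function(j)
    tcrossprod(xc[, (1 + j):Tt], xc[, 1:(Tt - j)]) / Tt)
  # [A1 A2] [[C0, C1], [C1', C0]] = [C1, C2]
  R <- rbind(cbind(C[[1]], C[[2]]), cbind(t(C[[2]]), C[[1]]))
  Adir <- cbind(C[[2]], C[[3]]) %*% solve(R)
  expect_equal(cbind(fl$coefficients[, , 1], fl$coefficients[, , 2]),
               Adir, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("BIC selects the generating order", {
  x <- simulate_sources(default_graph_spec(0.5), seed = 4)$values
  expect_equal(as.integer(select_order_bic(x, 10)), 2L)
  # white noise: the smallest order wins in the large majority of seeds
  wins <- vapply(1:10, function(s) {
    set.seed(s); as.integer(select_order_bic(matrix(rnorm(2 * 3000), 2), 6))
  }, 1L)
  expect_gte(mean(wins == 1L), 0.8)
  expect_error(select_order_bic(matrix(rnorm(8), 2), p_max = 10),
               "insufficient samples")
})

test_that("conditional GC magnitude matches a brute-force bivariate oracle", {
  # y <- a x(t-1): F_{x->y} has closed form ln(1 + a^2 var(x) / sigma_y^2)
  a <- 0.6
  A <- rbind(c(0.5, 0), c(a, 0.3))
  x <- simulate_var(A, 1e6, seed = 5)
  m <- gc_magnitude(x, 1)
  # brute force: explicit restricted/full residual variances via lm
  y2 <- x[2, 2:ncol(x)]
  full <- sum(resid(lm(y2 ~ 0 + x[2, 1:(ncol(x) - 1)] +
                         x[1, 1:(ncol(x) - 1)]))^2)
  restr <- sum(resid(lm(y2 ~ 0 + x[2, 1:(ncol(x) - 1)]))^2)
  expect_equal(m[2, 1], log(restr / full), tolerance = 0.02)
  # reverse direction is null
  expect_lt(m[1, 2], 0.01)
  expect_true(all(is.na(diag(m))))
})

test_that("magnitudes are invariant to channel-wise rescaling", {
  x <- simulate_sources(default_graph_spec(0.5), n_samples = 4000,
                        seed = 6)$values
  m1 <- gc_magnitude(x, 2)
  m2 <- gc_magnitude(diag(c(10, 0.1, 3, 0.5)) %*% x, 2)
  expect_equal(m1, m2, tolerance = 1e-8)
})

test_that("the largest magnitudes at high coupling are the true edges", {
  wins <- 0; n <- 16
  truth <- c("3<-1", "3<-2", "2<-3", "4<-3")
  for (r in seq_len(n)) {
    x <- simulate_sources(default_graph_spec(0.7), seed = 300 + r)$values
    m <- gc_magnitude(x, 2)
    top <- order(-m)[1:4]
    lab <- paste0(row(m)[top], "<-", col(m)[top])
    wins <- wins + setequal(lab, truth)
  }
  expect_gt(wins / n, 0.5)
})

test_that("edge testing applies the printed Bonferroni rule", {
  x <- simulate_sources(default_graph_spec(0.5), n_samples = 5000,
                        seed = 7)$values
  g <- gc_edges(x, 2, alpha_nominal = 0.01)
  expect_equal(g$threshold, 0.01 / 12)
  expect_true(all(g$f_statistics[!is.na(g$f_statistics)] >= 0))
  expect_false(any(diag(g$adjacency)))
  expect_identical(g$adjacency,
                   !is.na(g$p_values) & g$p_values < 0.01 / 12)
  td <- tidy(g)
  expect_equal(nrow(td), 12)
  expect_equal(sum(td$significant), sum(g$adjacency))
  gl <- glance(g)
  expect_equal(gl$n_edges, sum(g$adjacency))
})

test_that("null p-values are uniform and familywise error is controlled", {
  # 500 independent-AR(1) null datasets: KS uniformity of one fixed
  # off-diagonal p-value, and the Bonferroni familywise rate
  pv <- numeric(500); fw <- logical(500)
  A <- diag(c(0.5, 0.4, 0.3))
  for (r in 1:500) {
    x <- simulate_var(A, 400, seed = 4000 + r)
    g <- gc_edges(x, 1, alpha_nominal = 0.01)
    pv[r] <- g$p_values[2, 1]
    fw[r] <- any(g$adjacency)
  }
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  # binomial 99% envelope for a true familywise rate of 0.01 at n = 500
  expect_lte(sum(fw), stats::qbinom(0.99, 500, 0.01))
})

test_that("trial pooling fits one model across trials", {
  spec <- default_graph_spec(0.5)
  x <- simulate_sources(spec, n_samples = 11000, seed = 8)$values
  trials <- lapply(1:200, function(tr) x[, (tr - 1) * 55 + 1:55])
  f <- fit_var(trials, 2)
  expect_equal(f$fit_mode, "ols")
  expect_equal(f$n_effective, 200 * 53)
  full <- fit_var(x[, 1:11000], 2, method = "ols")
  expect_equal(f$coefficients, full$coefficients, tolerance = 0.15)
  expect_error(fit_var(trials, 2, method = "lwr"), "single series")
})
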