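# super-Gaussian spatial patterns mixed by known time courses
make_mixture <- function(n_loc = 400, n_time = 150, seed = 1) {
  set.seed(seed)
  maps <- rbind(c(rep(0, 40), rexp(60), rep(0, n_loc - 100)),
                c(rep(0, 200), rexp(50), rep(0, n_loc - 250)))
  maps <- maps / sqrt(rowSums(maps^2))
  tc <- matrix(rnorm(2 * n_time), 2)
  list(maps = maps, tc = tc, data = t(maps) %*% tc + 0)
}

test_that("rank-1 data yields the single pattern up to sign and scale", {
  set.seed(2)
  map <- c(rep(0, 50), rexp(30), rep(0, 120))
  tc <- rnorm(80)
  data <- outer(map, tc)
  cs <- spatial_ica(data, seed = 1)
  expect_equal(nrow(cs$spatial_maps), 1)
  expect_gt(abs(cor(cs$spatial_maps[1, ], map)), 0.999)
  # unit norm and positive-peak sign convention
  expect_equal(sum(cs$spatial_maps[1, ]^2), 1)
  i <- which.max(abs(cs$spatial_maps[1, ]))
  expect_gt(cs$spatial_maps[1, i], 0)
})

test_that("orthogonal sparse patterns are recovered above 0.99", {
  mx <- make_mixture(seed = 3)
  cs <- spatial_ica(mx$data, n_max = 2, mode = "symmetric", seed = 4)
  co <- abs(cor(t(cs$spatial_maps), t(mx$maps)))
  expect_gt(max(co[, 1]), 0.99)
  expect_gt(max(co[, 2]), 0.99)
  # retained maps + courses reconstruct the noiseless data
  rec <- t(cs$spatial_maps) %*% cs$time_courses
  dc <- sweep(mx$data, 2, colMeans(mx$data))
  expect_gt(1 - sum((rec - dc)^2) / sum(dc^2), 0.99)
})

test_that("whitening reduction rules behave as documented", {
  mx <- make_mixture(seed = 5)
  noisy <- mx$data + 0.05 * matrix(rnorm(length(mx$data)), nrow(mx$data))
  wh_full <- ica_whiten(noisy)
  wh_fix <- ica_whiten(noisy, n_reduce = 2)
  wh_auto <- ica_whiten(noisy, n_reduce = "auto")
  expect_gt(wh_full$rank, 2)
  expect_equal(wh_fix$rank, 2)
  # auto keeps the above-floor dimensions: at least the two patterns,
  # far fewer than the full rank
  expect_gte(wh_auto$rank, 2)
  expect_lt(wh_auto$rank, wh_full$rank / 4)
  # exactly low-rank data keeps all structural dimensions under "auto"
  expect_equal(ica_whiten(mx$data, n_reduce = "auto")$rank, 2)
  expect_error(spatial_ica(cbind(noisy, NA)), "finite")
})

test_that("time-arrangement output keeps maps and courses in their slots", {
  mx <- make_mixture(seed = 6)
  # transpose roles: independence across time needs non-Gaussian courses
  set.seed(7)
  tc <- rbind(rexp(500) * sign(rnorm(500)), rexp(500) * sign(rnorm(500)))
  maps <- matrix(rnorm(2 * 30), 2, 30)
  data <- t(maps) %*% tc                  # 30 locations x 500 times
  cs <- spatial_ica(data, mode = "symmetric", independence = "time",
                    seed = 8)
  expect_equal(ncol(cs$spatial_maps), 30)
  expect_equal(ncol(cs$time_courses), 500)
  co <- abs(cor(t(cs$time_courses), t(tc)))
  expect_gt(max(co[, 1]), 0.98)
  expect_gt(max(co[, 2]), 0.98)
  rec <- t(cs$spatial_maps) %*% cs$time_courses
  dc <- data - rowMeans(data)
  expect_gt(1 - sum((rec - dc)^2) / sum(dc^2), 0.98)
})

test_that("consensus is invariant to permutations and sign flips", {
  mx <- make_mixture(seed = 9)
  noisy <- mx$data + 0.02 * matrix(rnorm(length(mx$data)), nrow(mx$data))
  base <- spatial_ica(noisy, n_max = 2, mode = "symmetric", seed = 1)
  flip <- base
  flip$spatial_maps <- -base$spatial_maps[2:1, ]
  flip$time_courses <- -base$time_courses[2:1, ]
  c1 <- consensus_components(list(base, base, base), data = noisy)
  c2 <- consensus_components(list(base, flip, base), data = noisy)
  expect_equal(nrow(c1$spatial_maps), 2)
  expect_equal(abs(c1$spatial_maps %*% t(c2$spatial_maps)),
               diag(2), tolerance = 1e-6, ignore_attr = TRUE)
  # 20 identical runs: centroids equal the run's components
  c20 <- consensus_components(rep(list(base), 20), data = noisy)
  expect_equal(abs(c20$spatial_maps %*% t(base$spatial_maps)), diag(2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("consensus drops patterns that do not recur", {
  mx <- make_mixture(seed = 10)
  noisy <- mx$data + 0.02 * matrix(rnorm(length(mx$data)), nrow(mx$data))
  base <- spatial_ica(noisy, n_max = 2, mode = "symmetric", seed = 1)
  rogue <- base
  set.seed(11)
  rogue$spatial_maps <- matrix(rnorm(2 * ncol(base$spatial_maps)), 2)
  rogue$spatial_maps <- rogue$spatial_maps /
    sqrt(rowSums(rogue$spatial_maps^2))
  cc <- consensus_components(list(base, base, base, rogue),
                             data = noisy, min_occurrence = 0.5)
  expect_equal(nrow(cc$spatial_maps), 2)
  # nothing recurring: empty set with a warning
  r2 <- rogue
  set.seed(12)
  r2$spatial_maps <- matrix(rnorm(2 * ncol(base$spatial_maps)), 2)
  r2$spatial_maps <- r2$spatial_maps / sqrt(rowSums(r2$spatial_maps^2))
  expect_warning(e <- consensus_components(list(rogue, r2), data = noisy,
                                           min_occurrence = 0.9),
                 "min_occurrence")
  expect_equal(nrow(e$spatial_maps), 0)
})

test_that("screening keeps the requested subset", {
  mx <- make_mixture(seed = 13)
  cs <- spatial_ica(mx$data, n_max = 2, mode = "symmetric", seed = 4)
  expect_identical(screen_components(cs)$spatial_maps, cs$spatial_maps)
  s1 <- screen_components(cs, exclude = 2)
  expect_equal(nrow(s1$spatial_maps), 1)
  expect_equal(s1$provenance$screened_out, 2L)
  expect_error(screen_components(cs, exclude = 5), "out of range")
  s0 <- screen_components(cs, exclude = 1:2)
  expect_equal(nrow(s0$spatial_maps), 0)
})

test_that("map activation thresholds at |z| > 3", {
  m <- c(rep(0, 95), rep(8, 5))
  act <- map_activation(m)
  expect_equal(act$active, 96:100)
  expect_equal(mean(act$z), 0, tolerance = 1e-12)
})
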