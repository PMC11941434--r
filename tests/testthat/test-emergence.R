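test_that("Gaussian MI matches the bivariate closed form", {
  for (r in c(0, 0.3, 0.6, 0.9)) {
    pair <- corr_pair(100, r, seed = 31)
    expect_equal(gaussian_mutual_information(pair$x, pair$y),
                 -0.5 * log(1 - r^2), tolerance = 1e-9)
  }
})

test_that("duplicated variables give a flagged infinite MI", {
  set.seed(32)
  x <- matrix(stats::rnorm(100), 50, 2)
  mi <- gaussian_mutual_information(x, x)
  expect_identical(unname(as.numeric(mi)), Inf)
  expect_identical(attr(mi, "flag"), "singular")
})

test_that("orthogonalised samples have zero MI", {
  pair <- corr_pair(80, 0, seed = 33)
  expect_lt(gaussian_mutual_information(pair$x, pair$y), 1e-10)
})

test_that("MI is symmetric and affine-invariant", {
  set.seed(34)
  X <- matrix(stats::rnorm(200), 100, 2)
  Y <- X %*% matrix(c(1, 0.4, 0.4, 1), 2) + matrix(stats::rnorm(200), 100, 2)
  m1 <- gaussian_mutual_information(X, Y)
  expect_equal(m1, gaussian_mutual_information(Y, X), tolerance = 1e-10)
  A <- matrix(c(2, 0.3, -1, 0.7), 2)
  B <- matrix(c(0.5, -2, 1.5, 3), 2)
  m2 <- gaussian_mutual_information(X %*% A, Y %*% B + 5)
  expect_equal(m1, m2, tolerance = 1e-6)
  expect_gte(m1, 0)
})

test_that("MI estimator rejects bad input and converts units", {
  expect_error(gaussian_mutual_information(matrix(0, 3, 2), matrix(0, 3, 2)),
               "too few samples")
  expect_error(gaussian_mutual_information(c(1, NA, 3, 4, 5), c(1, 2, 3, 4, 5)),
               "non-finite")
  pair <- corr_pair(60, 0.6, seed = 35)
  nats <- gaussian_mutual_information(pair$x, pair$y)
  bits <- gaussian_mutual_information(pair$x, pair$y,
                                      emergence_config(mi_units = "bits"))
  expect_equal(bits, nats / log(2), tolerance = 1e-12)
})

test_that("Psi reaches the redundancy limit with duplicated micros", {
  set.seed(36)
  n <- 400
  V <- matrix(stats::rnorm(2 * n), n, 2)
  Vn <- 0.7 * V + 0.5 * matrix(stats::rnorm(2 * n), n, 2)
  micro <- lapply(1:10, function(i) V + 1e-6 * matrix(stats::rnorm(2 * n), n, 2))
  res <- psi_statistic(V, Vn, micro)
  expect_equal(res$psi, (1 - 10) * res$macro_mi,
               tolerance = 1e-3 * abs(res$macro_mi))
  expect_equal(res$psi, res$macro_mi - res$micro_mi_sum)
})

test_that("micros orthogonal to the future macro leave Psi = macro MI", {
  set.seed(37)
  n <- 300
  V <- stats::rnorm(n)
  Vn <- 0.8 * V + 0.3 * stats::rnorm(n)
  micro <- lapply(1:5, function(i) {
    z <- stats::rnorm(n)
    stats::residuals(stats::lm(z ~ Vn))  # exactly uncorrelated with Vn
  })
  res <- psi_statistic(cbind(V), cbind(Vn), lapply(micro, cbind))
  expect_equal(res$micro_mi_sum, 0, tolerance = 1e-9)
  expect_equal(res$psi, res$macro_mi, tolerance = 1e-9)
})

test_that("white-noise macro with informative micros makes Psi negative", {
  set.seed(38)
  n <- 300
  Vn <- stats::rnorm(n)
  V <- stats::residuals(stats::lm(stats::rnorm(n) ~ Vn))
  micro <- lapply(1:3, function(i) cbind(Vn + 0.5 * stats::rnorm(n)))
  res <- psi_statistic(cbind(V), cbind(Vn), micro)
  expect_lte(res$psi, 0)
  expect_lt(res$macro_mi, 1e-9)
})

test_that("psi_statistic enforces equal sample counts", {
  expect_error(psi_statistic(matrix(0, 10, 1), matrix(0, 9, 1),
                             list(matrix(0, 10, 1))),
               "same n")
})

test_that("window counting follows the interval arithmetic", {
  p <- null_params(half_length_s = 120, shot_hazard = 0)
  traj <- generate_team_trajectory(p, rep(TRUE, 120), seed = 40)
  ser <- com_series_from_traj(traj)
  ps <- sliding_window_psi(ser, emergence_config(window_s = 60, step_s = 1))
  expect_equal(nrow(ps), 61)
  expect_equal(ps$t_end, 60:120)
  expect_equal(attr(ps, "n_pairs"), 59)
  ps2 <- sliding_window_psi(ser, emergence_config(window_s = 60, step_s = 60))
  expect_equal(ps2$t_end, c(60, 120))
  expect_error(sliding_window_psi(ser, emergence_config(window_s = 121)),
               "shorter")
})

test_that("sliding-window engine agrees with direct psi_statistic", {
  p <- null_params(half_length_s = 300, shot_hazard = 0)
  traj <- generate_team_trajectory(p, rep(TRUE, 300), seed = 41)
  ser <- com_series_from_traj(traj)
  ps <- sliding_window_psi(ser, emergence_config(window_s = 60, step_s = 80))
  for (k in seq_len(nrow(ps))) {
    e <- ps$t_end[k]
    idx <- (e - 59):(e - 1)
    direct <- psi_statistic(ser$macro[idx, ], ser$macro[idx + 1, ],
                            ser$micro[idx, , ])
    expect_equal(ps$psi[k], direct$psi, tolerance = 1e-9)
    expect_equal(ps$macro_mi[k], direct$macro_mi, tolerance = 1e-9)
  }
  ok <- !is.na(ps$psi)
  expect_equal(ps$psi[ok], ps$macro_mi[ok] - ps$micro_mi_sum[ok])
})

test_that("degenerate and masked windows are flagged", {
  L <- 100
  ser <- structure(list(feature_name = "com", team = "home", times = 1:L,
                        macro = matrix(1.5, L, 2),
                        micro = array(stats::rnorm(L * 10 * 2), c(L, 10, 2)),
                        valid = rep(TRUE, L), n_players = 10),
                   class = "macro_micro_series")
  ps <- sliding_window_psi(ser, emergence_config())
  expect_true(all(ps$flag == "degenerate"))
  expect_true(all(is.na(ps$psi)))

  p <- null_params(half_length_s = 200, shot_hazard = 0)
  traj <- generate_team_trajectory(p, rep(TRUE, 200), seed = 42)
  ser2 <- com_series_from_traj(traj)
  ser2$valid[100] <- FALSE
  ps2 <- sliding_window_psi(ser2, emergence_config())
  hit <- ps2$t_end >= 100 & ps2$t_end <= 159
  expect_true(all(ps2$flag[hit] == "masked"))
  expect_true(all(ps2$flag[!hit] == ""))
})

test_that("emergence config rejects invalid settings", {
  expect_error(emergence_config(window_s = 1, lag_s = 1), "exceed")
  expect_error(emergence_config(lag_s = 0), "lag_s")
  expect_error(emergence_config(ridge = -1), "ridge")
  expect_error(emergence_config(order_l = 2), "order_l")
})
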