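# Small tracking fixture: full player grids for both teams at given times.
make_frames <- function(times, n_players = 10, jitter = 0) {
  grid <- expand.grid(t = times, team = c("home", "away"),
                      player = seq_len(n_players),
                      stringsAsFactors = FALSE)
  grid$x <- (grid$player - (n_players + 1) / 2) * 4 +
    ifelse(grid$team == "home", -10, 10) + jitter * sin(grid$t + grid$player)
  grid$y <- (grid$player %% 5 - 2) * 8 + jitter * cos(grid$t * 2 + grid$player)
  grid
}

make_tracking <- function(times, half_bounds = NULL, n_players = 10,
                          jitter = 0, sample_rate_hz = 1) {
  match_tracking(make_frames(times, n_players, jitter),
                 half_bounds = half_bounds,
                 sample_rate_hz = sample_rate_hz, validate = FALSE)
}

# Independent brute-force oracle for the weighted clustering coefficient:
# literal triple loop over ordered neighbour pairs.
brute_node_clustering <- function(W, A, i) {
  n <- nrow(W)
  k_i <- sum(A[i, ])
  acc <- 0
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      acc <- acc + (W[i, j] + W[i, k]) / 2 * A[j, k]
    }
  }
  acc / (k_i * (k_i - 1))
}

# Wrap one team trajectory into a centre-of-mass macro/micro series.
com_series_from_traj <- function(traj) {
  L <- nrow(traj$centre)
  structure(list(feature_name = "com", team = "home", times = seq_len(L),
                 macro = cbind(rowMeans(traj$positions[, , 1]),
                               rowMeans(traj$positions[, , 2])),
                 micro = traj$positions, valid = rep(TRUE, L),
                 n_players = dim(traj$positions)[2]),
            class = "macro_micro_series")
}

# Deterministic construction of a scalar pair with exact sample correlation r.
corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  z <- z / sqrt(mean(z^2))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}

# Generator defaults used across simulation tests.
null_params <- function(...) {
  synthetic_params(phi_p = 0.65, phi_n = 0.65,
                   gamma_attack = 1, gamma_defend = 1, ...)
}
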