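#' Configuration of the emergence estimator
#'
#' @param window_s sliding-window length in seconds (must exceed `lag_s`).
#' @param step_s step between consecutive window ends, seconds.
#' @param lag_s prediction lag between the micro/macro state at `t` and the
#'   future macro state at `t' = t + lag_s`, seconds.
#' @param mi_units `"nats"` (natural log, default) or `"bits"`.
#' @param ridge non-negative ridge added to the diagonal of the joint
#'   covariance before taking determinants; guards near-singular windows.
#' @param order_l decomposition order; only individual micro variables
#'   (`order_l = 1`) are supported.
#' @return list of class `emergence_config`.
#' @export
emergence_config <- function(window_s = 60, step_s = 1, lag_s = 1,
                             mi_units = c("nats", "bits"), ridge = 1e-10,
                             order_l = 1) {
  mi_units <- match.arg(mi_units)
  if (lag_s < 1) stop("lag_s must be >= 1")
  if (window_s <= lag_s) stop("window_s must exceed lag_s")
  if (step_s < 1) stop("step_s must be >= 1")
  if (ridge < 0) stop("ridge must be >= 0")
  if (order_l != 1) stop("only order_l = 1 is supported")
  structure(list(window_s = window_s, step_s = step_s, lag_s = lag_s,
                 mi_units = mi_units, ridge = ridge, order_l = order_l),
            class = "emergence_config")
}

# Internal: log-determinant of a small symmetric positive-definite matrix.
# Returns NA on (numerical) non-positive-definiteness.
logdet_sym <- function(S) {
  p <- nrow(S)
  if (p == 1) {
    if (S[1, 1] <= 0) return(NA_real_)
    return(log(S[1, 1]))
  }
  if (p == 2) {
    d <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (d <= 0 || S[1, 1] <= 0) return(NA_real_)
    return(log(d))
  }
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  2 * sum(log(diag(ch)))
}

#' Gaussian mutual information between two multivariate samples
#'
#' Closed-form Gaussian estimator: with maximum-likelihood (1/n) covariances,
#' `I(X; Y) = 0.5 * log( det(S_XX) det(S_YY) / det(S_[X,Y]) )`. A ridge is
#' added to the diagonal of the joint covariance before the block
#' determinants are taken; the estimate is clamped at 0 (negative values can
#' arise only through the ridge). If the joint covariance is singular (e.g.
#' `Y` duplicates `X` exactly) the function returns `Inf` with attribute
#' `flag = "singular"`.
#'
#' @param X,Y numeric vectors or matrices with one row per sample (`n` rows,
#'   `p` and `q` columns); `n >= p + q + 2` is required.
#' @param config an [emergence_config()]; only `mi_units` and `ridge` are
#'   used.
#' @return mutual information in the configured units.
#' @export
gaussian_mutual_information <- function(X, Y, config = emergence_config()) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of samples")
  p <- ncol(X)
  q <- ncol(Y)
  if (n < p + q + 2) {
    stop(sprintf("too few samples: n = %d < p + q + 2 = %d", n, p + q + 2))
  }
  Z <- cbind(X, Y)
  if (any(!is.finite(Z))) stop("non-finite values in X or Y")
  Zc <- sweep(Z, 2, colMeans(Z))
  C <- crossprod(Zc) / n
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(max(ev), 1e-300) * 1e-13) {
    return(structure(Inf, flag = "singular"))
  }
  diag(C) <- diag(C) + config$ridge
  la <- logdet_sym(C[seq_len(p), seq_len(p), drop = FALSE])
  lb <- logdet_sym(C[p + seq_len(q), p + seq_len(q), drop = FALSE])
  lab <- logdet_sym(C)
  if (anyNA(c(la, lb, lab))) return(structure(Inf, flag = "singular"))
  mi <- max(0.5 * (la + lb - lab), 0)
  if (config$mi_units == "bits") mi <- mi / log(2)
  mi
}

#' Practical causal-emergence criterion Psi for one sample set
#'
#' Computes `Psi = I(V_t; V_t') - sum_i I(X_t^i; V_t')`: the mutual
#' information that the macroscopic feature carries about its own future,
#' minus the summed information each microscopic variable carries about that
#' same future. Positive values indicate synergistic (emergent) macro-level
#' predictive power; negative values indicate redundancy-dominated dynamics
#' (every player individually predicts the future macro state, so the sum
#' overcounts).
#'
#' @param macro_t n x d matrix of macro states at time `t`.
#' @param macro_next n x d matrix of macro states at `t' = t + lag`.
#' @param micro_t list of n x d_i matrices (one per micro variable, e.g. per
#'   player), or an n x N x d array.
#' @param config an [emergence_config()].
#' @return list with `psi`, `macro_mi`, `micro_mi_sum` and the per-variable
#'   `micro_mi`; `psi = macro_mi - micro_mi_sum` exactly.
#' @export
psi_statistic <- function(macro_t, macro_next, micro_t,
                          config = emergence_config()) {
  macro_t <- as.matrix(macro_t)
  macro_next <- as.matrix(macro_next)
  if (is.array(micro_t) && length(dim(micro_t)) == 3) {
    micro_t <- lapply(seq_len(dim(micro_t)[2]), function(i) {
      matrix(micro_t[, i, ], nrow = dim(micro_t)[1])
    })
  }
  n <- nrow(macro_t)
  sizes <- c(nrow(macro_next), vapply(micro_t, nrow, 0L))
  if (any(sizes != n)) stop("all sample sets must share the same n")
  macro_mi <- gaussian_mutual_information(macro_t, macro_next, config)
  micro_mi <- vapply(micro_t, function(Xi) {
    as.numeric(gaussian_mutual_information(Xi, macro_next, config))
  }, 0)
  list(psi = as.numeric(macro_mi) - sum(micro_mi),
       macro_mi = as.numeric(macro_mi),
       micro_mi_sum = sum(micro_mi),
       micro_mi = micro_mi)
}

#' Sliding-window Psi over a macro/micro feature series
#'
#' For each window end `e` (stepping by `step_s`), uses the samples
#' `t in [e - window_s + 1, e - lag_s]` paired with `t' = t + lag_s` — all
#' `window_s - lag_s` pairs lying inside the window — to estimate the macro
#' mutual information, the per-player micro terms, and their difference Psi.
#' Windows are anchored at their end time, so a value at `e` summarises the
#' `window_s` seconds up to and including `e`. Windows containing masked
#' frames are flagged `"masked"`; windows whose macro signal is (numerically)
#' constant are flagged `"degenerate"`; both carry `NA` Psi.
#'
#' Implementation note: window moments are assembled from cumulative sums of
#' the (globally centred) feature columns and their pairwise products, so the
#' cost is linear in the series length and independent of `window_s`.
#'
#' @param series a `macro_micro_series` from [compute_feature_series()],
#'   sampled at 1 Hz.
#' @param config an [emergence_config()].
#' @return data.frame of class `psi_series` with columns `t_end`, `psi`,
#'   `macro_mi`, `micro_mi_sum`, `flag`; attributes `feature_name`, `team`,
#'   `config`.
#' @export
sliding_window_psi <- function(series, config = emergence_config()) {
  times <- series$times
  T_len <- length(times)
  if (T_len > 1 && any(abs(diff(times) - 1) > 1e-9)) {
    stop("series must be sampled at 1 Hz with uniform spacing")
  }
  window <- config$window_s
  lag <- config$lag_s
  step <- config$step_s
  if (T_len < window) stop("series shorter than one window")
  dv <- ncol(series$macro)
  n_p <- dim(series$micro)[2]
  dx <- dim(series$micro)[3]
  n_pairs <- window - lag
  min_n <- max(dv + dv, dx + dv) + 2
  if (n_pairs < min_n) {
    stop(sprintf("window too short: %d pairs < %d required", n_pairs, min_n))
  }

  micro_flat <- matrix(series$micro, T_len, n_p * dx)
  rows_t <- seq_len(T_len - lag)
  Z <- cbind(series$macro[rows_t, , drop = FALSE],
             series$macro[rows_t + lag, , drop = FALSE],
             micro_flat[rows_t, , drop = FALSE])
  Z <- sweep(Z, 2, colMeans(Z))  # global centring for numerical stability
  nc <- ncol(Z)

  pair_i <- rep(seq_len(nc), times = nc:1)
  pair_j <- unlist(lapply(seq_len(nc), function(i) i:nc))
  IDX <- matrix(0L, nc, nc)
  IDX[cbind(pair_i, pair_j)] <- seq_along(pair_i)
  IDX[cbind(pair_j, pair_i)] <- seq_along(pair_i)

  S1 <- rbind(0, apply(Z, 2, cumsum))
  P <- Z[, pair_i, drop = FALSE] * Z[, pair_j, drop = FALSE]
  SP <- rbind(0, apply(P, 2, cumsum))
  bad <- cumsum(c(0, !series$valid))

  ends <- seq(window, T_len, by = step)
  r1 <- ends - window + 1
  r2 <- ends - lag
  n <- n_pairs
  M <- (S1[r2 + 1, , drop = FALSE] - S1[r1, , drop = FALSE]) / n
  CV <- (SP[r2 + 1, , drop = FALSE] - SP[r1, , drop = FALSE]) / n -
    M[, pair_i, drop = FALSE] * M[, pair_j, drop = FALSE]

  ix_macro <- seq_len(dv)
  ix_next <- dv + seq_len(dv)
  ix_micro <- lapply(seq_len(n_p), function(i) 2 * dv + (seq_len(dx) - 1) * n_p + i)
  ridge <- config$ridge
  to_bits <- config$mi_units == "bits"
  n_win <- length(ends)

  diag_cols <- IDX[cbind(seq_len(nc), seq_len(nc))]
  CVr <- CV
  CVr[, diag_cols] <- CVr[, diag_cols] + ridge

  # vectorised log-determinant over windows for a set of Z columns
  vlogdet <- function(cols) {
    m <- length(cols)
    pick <- function(a, b) CVr[, IDX[cols[a], cols[b]]]
    if (m == 1) return(log(pick(1, 1)))
    if (m == 2) {
      return(log(pick(1, 1) * pick(2, 2) - pick(1, 2)^2))
    }
    if (m == 3) {
      s11 <- pick(1, 1); s12 <- pick(1, 2); s13 <- pick(1, 3)
      s22 <- pick(2, 2); s23 <- pick(2, 3); s33 <- pick(3, 3)
      return(log(s11 * (s22 * s33 - s23^2) - s12 * (s12 * s33 - s23 * s13) +
                   s13 * (s12 * s23 - s22 * s13)))
    }
    # m == 4: Schur complement on the leading 2x2 block
    s11 <- pick(1, 1); s12 <- pick(1, 2); s13 <- pick(1, 3); s14 <- pick(1, 4)
    s22 <- pick(2, 2); s23 <- pick(2, 3); s24 <- pick(2, 4)
    s33 <- pick(3, 3); s34 <- pick(3, 4); s44 <- pick(4, 4)
    dA <- s11 * s22 - s12^2
    t11 <- s13^2 * s22 - 2 * s13 * s23 * s12 + s23^2 * s11
    t12 <- s13 * s14 * s22 - (s13 * s24 + s14 * s23) * s12 + s23 * s24 * s11
    t22 <- s14^2 * s22 - 2 * s14 * s24 * s12 + s24^2 * s11
    m11 <- s33 - t11 / dA
    m12 <- s34 - t12 / dA
    m22 <- s44 - t22 / dA
    log(dA) + log(m11 * m22 - m12^2)
  }
  block_mi <- function(ix, iy) {
    mi <- suppressWarnings(
      0.5 * (vlogdet(ix) + vlogdet(iy) - vlogdet(c(ix, iy))))
    ifelse(is.nan(mi) | is.infinite(mi), NA_real_, pmax(mi, 0))
  }

  macro_mi <- block_mi(ix_macro, ix_next)
  micro_sum <- rep(0, n_win)
  for (ix in ix_micro) micro_sum <- micro_sum + block_mi(ix, ix_next)
  if (to_bits) {
    macro_mi <- macro_mi / log(2)
    micro_sum <- micro_sum / log(2)
  }
  psi <- macro_mi - micro_sum

  flag <- character(n_win)
  flag[is.na(psi)] <- "singular"
  degen_cols <- diag_cols[c(ix_macro, ix_next)]
  degen <- rowSums(CV[, degen_cols, drop = FALSE] < 1e-12) > 0
  flag[degen] <- "degenerate"
  masked <- (bad[ends + 1] - bad[r1]) > 0
  flag[masked] <- "masked"
  psi[flag != ""] <- NA_real_
  macro_mi[flag != ""] <- NA_real_
  micro_sum[flag != ""] <- NA_real_

  out <- data.frame(t_end = times[ends], psi = psi, macro_mi = macro_mi,
                    micro_mi_sum = micro_sum, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("psi_series", "data.frame")
  attr(out, "feature_name") <- series$feature_name
  attr(out, "team") <- series$team
  attr(out, "config") <- config
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Sliding-window Psi for a whole match
#'
#' Convenience wrapper: preprocesses a match (half segmentation, red-card
#' exclusion, velocity differentiation), computes the requested feature for
#' one team in each half, and concatenates the per-half [sliding_window_psi()]
#' series on the match clock. Windows never cross the half boundary.
#'
#' @param tracking a `match_tracking` for the full match.
#' @param events the matching `event_log`.
#' @param team `"home"` or `"away"`.
#' @param feature_name,variant,eps see [compute_feature_series()].
#' @param config an [emergence_config()].
#' @return a `psi_series` covering both halves.
#' @export
match_psi <- function(tracking, events, team, feature_name = "com",
                      variant = c("com_to_center", "mean_distance"),
                      eps = 0.1, config = emergence_config()) {
  variant <- match.arg(variant)
  tracking <- apply_exclusions(tracking, events)
  halves <- segment_halves(tracking, events)
  pieces <- lapply(halves, function(h) {
    h <- differentiate_positions(h)
    ser <- compute_feature_series(h, team, feature_name, variant = variant,
                                  eps = eps)
    sliding_window_psi(ser, config)
  })
  out <- do.call(rbind, pieces)
  class(out) <- c("psi_series", "data.frame")
  attr(out, "feature_name") <- feature_name
  attr(out, "team") <- team
  attr(out, "config") <- config
  out
}
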