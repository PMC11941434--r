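#' Extract pre-shot Psi curves
#'
#' For every shot, reads the Psi values whose windows end in the 60 s (or
#' `duration_s`) ending at the frame immediately preceding the shot: window
#' ends `shot - duration_s .. shot - 1`. The shooting team's curve is
#' labelled attacker and the opponent's defender, and these labels are kept
#' for the whole interval even if possession changes hands inside it. Shots
#' without complete, unflagged Psi coverage for both teams are dropped, with
#' the reason recorded.
#'
#' @param psi named list with elements `home` and `away`, each a `psi_series`
#'   covering the match.
#' @param events an `event_log` containing the shots.
#' @param duration_s pre-event interval length, seconds.
#' @return list of class `event_aligned_curves`: `rel_time` (-duration..-1),
#'   `attacker` and `defender` (n_shots x duration matrices), `shots`
#'   (retained shots), `dropped` (discarded shots with reasons).
#' @export
extract_pre_event_curves <- function(psi, events, duration_s = 60) {
  stopifnot(all(c("home", "away") %in% names(psi)))
  shots <- events$events[events$events$event_type == "shot", , drop = FALSE]
  rel_time <- seq(-duration_s, -1)
  att <- list()
  def <- list()
  kept <- list()
  dropped <- list()
  for (i in seq_len(nrow(shots))) {
    s <- shots$t[i]
    team <- shots$team[i]
    other <- setdiff(c("home", "away"), team)
    need <- seq(s - duration_s, s - 1)
    a <- psi_at(psi[[team]], need)
    d <- psi_at(psi[[other]], need)
    if (anyNA(a) || anyNA(d)) {
      dropped[[length(dropped) + 1]] <- data.frame(
        t = s, team = team, reason = "incomplete psi coverage")
      next
    }
    att[[length(att) + 1]] <- a
    def[[length(def) + 1]] <- d
    kept[[length(kept) + 1]] <- shots[i, , drop = FALSE]
  }
  if (!length(att)) stop("no shots with complete pre-event Psi coverage")
  structure(list(rel_time = rel_time,
                 attacker = do.call(rbind, att),
                 defender = do.call(rbind, def),
                 shots = do.call(rbind, kept),
                 dropped = if (length(dropped)) do.call(rbind, dropped)),
            class = "event_aligned_curves")
}

# Internal: psi values at given window-end times; NA where absent or flagged.
psi_at <- function(psi_series, t_ends) {
  idx <- match(t_ends, psi_series$t_end)
  psi_series$psi[idx]
}

#' Sample matched random baseline intervals
#'
#' Draws `n_events` pseudo-event times uniformly inside one half, subject to
#' full Psi coverage of the preceding `duration_s` seconds (the same
#' windowing as the real events), and returns their Psi curves. Placements
#' may overlap shot intervals; sampling is reproducible from `seed`.
#'
#' @param psi a `psi_series` for the team providing the baseline.
#' @param half_bounds one-row data.frame (`start`, `end`) or length-2 vector.
#' @param n_events number of baseline intervals to draw.
#' @param seed integer RNG seed.
#' @param duration_s interval length, seconds.
#' @return list with `times` (pseudo-event times), `curves`
#'   (n_events x duration matrix) and `rel_time`.
#' @export
sample_baseline_intervals <- function(psi, half_bounds, n_events, seed,
                                      duration_s = 60) {
  if (is.data.frame(half_bounds)) {
    half_bounds <- c(half_bounds$start[1], half_bounds$end[1])
  }
  if (diff(half_bounds) + 1 < duration_s) {
    stop("half shorter than one baseline interval")
  }
  ok <- !is.na(psi$psi) & psi$t_end >= half_bounds[1] &
    psi$t_end <= half_bounds[2]
  ok_t <- psi$t_end[ok]
  candidates <- c()
  if (length(ok_t)) {
    # pseudo-event time b is valid when all of b-duration..b-1 are available;
    # count availability with a rolling sum over the half's integer clock
    start <- half_bounds[1]
    grid <- seq(start, half_bounds[2])
    cum <- cumsum(c(0, grid %in% ok_t))
    bs <- seq(start + duration_s, half_bounds[2] + 1)
    n_avail <- cum[bs - start + 1] - cum[bs - duration_s - start + 1]
    candidates <- bs[n_avail == duration_s]
  }
  rel_time <- seq(-duration_s, -1)
  if (n_events == 0) {
    return(list(times = numeric(0),
                curves = matrix(0, 0, duration_s), rel_time = rel_time))
  }
  if (!length(candidates)) stop("no valid baseline placement in half")
  set.seed(seed)
  bs <- sample(candidates, n_events,
               replace = n_events > length(candidates))
  curves <- t(vapply(bs, function(b) {
    psi_at(psi, seq(b - duration_s, b - 1))
  }, numeric(duration_s)))
  list(times = bs, curves = curves, rel_time = rel_time)
}

#' Per-timepoint group comparison with Bonferroni correction
#'
#' Runs a two-sample Welch t-test at every relative timepoint between two
#' groups of event-aligned curves and marks a timepoint significant when its
#' p-value falls below `alpha / n_comparisons`. Timepoints with degenerate
#' variance in both groups are flagged and reported non-significant.
#'
#' @param group_a,group_b matrices of curves (events x timepoints).
#' @param alpha family-wise significance level.
#' @param n_comparisons Bonferroni divisor; defaults to the number of
#'   timepoints.
#' @return list with `significant` (logical per timepoint), `p_value`,
#'   `threshold`, `degenerate`.
#' @export
timepoint_significance <- function(group_a, group_b, alpha = 0.05,
                                   n_comparisons = NULL) {
  group_a <- rbind(group_a)
  group_b <- rbind(group_b)
  if (ncol(group_a) != ncol(group_b)) {
    stop("groups must share the timepoint grid")
  }
  if (nrow(group_a) < 2 || nrow(group_b) < 2) {
    stop("need at least 2 curves per group")
  }
  if (is.null(n_comparisons)) n_comparisons <- ncol(group_a)
  pv <- vapply(seq_len(ncol(group_a)), function(j) {
    a <- group_a[, j]
    b <- group_b[, j]
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) return(NA_real_)
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }, 0)
  threshold <- alpha / n_comparisons
  sig <- !is.na(pv) & pv < threshold
  list(significant = sig, p_value = pv, threshold = threshold,
       degenerate = is.na(pv))
}

#' Linear trend of an event-aligned mean curve
#'
#' Ordinary least-squares regression of the across-event mean Psi curve on
#' relative time (seconds). A constant curve yields slope 0, R-squared 0 and
#' is flagged.
#'
#' @param curve numeric vector, typically the across-event mean Psi at each
#'   relative timepoint.
#' @param times relative times in seconds (same length as `curve`).
#' @return list of class `trend_result`: `slope` (Psi per second),
#'   `intercept`, `r_squared`, `p_value`, `flagged`.
#' @export
trend_regression <- function(curve, times = seq_along(curve)) {
  if (length(curve) < 3) stop("need at least 3 points for a trend")
  if (length(times) != length(curve)) stop("times and curve lengths differ")
  if (stats::sd(curve) < 1e-14) {
    return(structure(list(slope = 0, intercept = mean(curve), r_squared = 0,
                          p_value = NA_real_, flagged = TRUE),
                     class = "trend_result"))
  }
  fit <- stats::lm(curve ~ times)
  sm <- suppressWarnings(summary(fit))  # exact lines warn about perfect fit
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 flagged = FALSE),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> slope = %.4g /s, R^2 = %.3f, p = %.3g%s\n",
              x$slope, x$r_squared, x$p_value,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Pool shot-locked curves over several matches
#'
#' Computes Psi for both teams of every match, extracts the attacker and
#' defender pre-shot curves, and draws one matched random baseline interval
#' per retained shot from the shooting team's Psi series in the same half.
#' Curves from all matches and halves are pooled.
#'
#' @param matches list of `list(tracking =, events =)` pairs, e.g. from
#'   [generate_match()].
#' @param feature_name macroscopic feature to analyse.
#' @param config an [emergence_config()].
#' @param seed seed for baseline placement.
#' @param duration_s pre-event interval length, seconds.
#' @param variant relative-distance variant.
#' @return list with pooled `attacker`, `defender`, `baseline` matrices,
#'   `rel_time` and the per-match retained shot counts.
#' @export
pool_shot_curves <- function(matches, feature_name = "com",
                             config = emergence_config(), seed = 1,
                             duration_s = 60,
                             variant = "com_to_center") {
  att <- def <- bas <- list()
  n_shots <- integer(length(matches))
  for (m in seq_along(matches)) {
    mt <- matches[[m]]
    psi <- list(
      home = match_psi(mt$tracking, mt$events, "home", feature_name,
                       variant = variant, config = config),
      away = match_psi(mt$tracking, mt$events, "away", feature_name,
                       variant = variant, config = config))
    curves <- extract_pre_event_curves(psi, mt$events, duration_s)
    att[[m]] <- curves$attacker
    def[[m]] <- curves$defender
    n_shots[m] <- nrow(curves$attacker)
    hb <- mt$events$half_bounds
    base_m <- list()
    for (i in seq_len(nrow(curves$shots))) {
      s <- curves$shots[i, ]
      h <- half_of_time(s$t, hb)
      base_m[[i]] <- sample_baseline_intervals(
        psi[[s$team]], hb[hb$half == h, ], 1,
        seed = (seed * 1009 + m * 101 + i) %% 2147483647,
        duration_s = duration_s)$curves
    }
    bas[[m]] <- do.call(rbind, base_m)
  }
  list(rel_time = seq(-duration_s, -1),
       attacker = do.call(rbind, att),
       defender = do.call(rbind, def),
       baseline = do.call(rbind, bas),
       n_shots = n_shots)
}
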