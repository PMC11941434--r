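#' Possession rate of a team over one half
#'
#' Fraction of the half during which the team holds the ball, computed from
#' the per-second possession label sequence: seconds labelled with the team
#' divided by the half duration (unlabelled seconds count in the denominator
#' only).
#'
#' @param events an `event_log` whose possession series covers the half.
#' @param half_bounds one-row data.frame (`start`, `end`) or length-2 vector.
#' @param team `"home"` or `"away"`.
#' @return possession rate in `[0, 1]`.
#' @export
possession_rate <- function(events, half_bounds, team) {
  if (is.data.frame(half_bounds)) {
    half_bounds <- c(half_bounds$start[1], half_bounds$end[1])
  }
  poss <- events$possession
  sel <- poss$t >= half_bounds[1] & poss$t <= half_bounds[2]
  if (!any(sel)) stop("possession labels do not cover the half")
  duration <- half_bounds[2] - half_bounds[1] + 1
  sum(poss$team[sel] == team, na.rm = TRUE) / duration
}

#' Mean Psi over one half
#'
#' Arithmetic mean of the Psi values of all non-flagged windows whose end
#' time falls inside the half.
#'
#' @param psi a `psi_series`.
#' @param half_bounds one-row data.frame (`start`, `end`) or length-2 vector.
#' @return mean Psi (errors if no valid window ends in the half).
#' @export
half_mean_psi <- function(psi, half_bounds) {
  if (is.data.frame(half_bounds)) {
    half_bounds <- c(half_bounds$start[1], half_bounds$end[1])
  }
  sel <- !is.na(psi$psi) & psi$t_end >= half_bounds[1] &
    psi$t_end <= half_bounds[2]
  if (!any(sel)) stop("no valid Psi window ends inside the half")
  mean(psi$psi[sel])
}

#' Half-level summaries for a set of matches
#'
#' Computes, per match, half and team, the mean Psi of one macroscopic
#' feature and the possession rate: the inputs of the home-vs-away
#' difference analysis.
#'
#' @param matches list of `list(tracking =, events =)` pairs.
#' @param feature_name macroscopic feature.
#' @param config an [emergence_config()].
#' @param variant relative-distance variant.
#' @return data.frame with columns `match`, `half`, `team`, `mean_psi`,
#'   `possession_rate`.
#' @export
summarize_halves <- function(matches, feature_name = "com",
                             config = emergence_config(),
                             variant = "com_to_center") {
  rows <- list()
  for (m in seq_along(matches)) {
    mt <- matches[[m]]
    hb <- mt$events$half_bounds
    for (team in c("home", "away")) {
      psi <- match_psi(mt$tracking, mt$events, team, feature_name,
                       variant = variant, config = config)
      for (i in seq_len(nrow(hb))) {
        rows[[length(rows) + 1]] <- data.frame(
          match = m, half = hb$half[i], team = team,
          mean_psi = half_mean_psi(psi, hb[i, ]),
          possession_rate = possession_rate(mt$events, hb[i, ], team))
      }
    }
  }
  do.call(rbind, rows)
}

#' Home-minus-away differences per (match, half)
#'
#' For every match and half with both teams summarised, returns the home
#' minus away difference in mean Psi and in possession rate — one scatter
#' point per (match, half). Halves missing a team are skipped with a
#' message.
#'
#' @param summaries data.frame as returned by [summarize_halves()].
#' @return data.frame with columns `match`, `half`, `d_psi`, `d_possession`.
#' @export
paired_differences <- function(summaries) {
  rows <- list()
  for (key in unique(paste(summaries$match, summaries$half))) {
    sub <- summaries[paste(summaries$match, summaries$half) == key, ,
                     drop = FALSE]
    home <- sub[sub$team == "home", , drop = FALSE]
    away <- sub[sub$team == "away", , drop = FALSE]
    if (nrow(home) != 1 || nrow(away) != 1) {
      message("skipping (match, half) = (", key, "): missing team summary")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      match = home$match, half = home$half,
      d_psi = home$mean_psi - away$mean_psi,
      d_possession = home$possession_rate - away$possession_rate)
  }
  do.call(rbind, rows)
}

#' Pearson correlation of paired differences
#'
#' Correlates the home-minus-away mean-Psi differences with the
#' home-minus-away possession-rate differences across (match, half) pairs.
#'
#' @param pairs data.frame from [paired_differences()].
#' @return list with Pearson `r`, two-sided `p`, and `n_pairs`.
#' @export
correlate_differences <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 (match, half) pairs")
  if (stats::sd(pairs$d_psi) == 0 || stats::sd(pairs$d_possession) == 0) {
    stop("degenerate differences: zero variance")
  }
  ct <- stats::cor.test(pairs$d_psi, pairs$d_possession, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(pairs))
}
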