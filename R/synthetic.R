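#' Parameters of the synthetic match generator
#'
#' The generator emulates the statistical structure that the causal-emergence
#' pipeline assumes in real tracking data: two teams of `n_players` outfield
#' players sampled at 1 Hz over two halves, a binary possession label sequence
#' following a symmetric two-state Markov chain, and shot events drawn by a
#' per-second hazard for the possessing team.
#'
#' Each team's latent centre \eqn{V_t} follows a mean-reverting AR(1) around a
#' possession-dependent attractor \eqn{c_t} (shifted towards the opponent goal
#' while in possession):
#' \deqn{V_{t+1} = c_{t+1} + \phi_{t+1} (V_t - c_{t+1}) + \eta_t,}
#' with persistence `phi_p` while in possession and `phi_n` otherwise, and
#' innovations scaled so the stationary spread of the centre around its
#' attractor is `sigma_macro` metres in each coordinate regardless of
#' \eqn{\phi}. Player `i` sits at \eqn{X_{i,t} = V_t + F_i + D_{i,t}} where
#' `F_i` is a fixed formation offset and `D` is per-player AR(1) idiosyncratic
#' jitter with persistence `rho_idio` and stationary SD `sigma_idio`. With
#' `center_idio = TRUE` (default) the jitter is mean-centred across the team
#' at every second, i.e. the deviations are formation-preserving: players
#' exchange space without displacing the team centre, so the centre of mass
#' coincides with \eqn{V_t} exactly. `sigma_idio` is the synergy/redundancy
#' dial: small jitter makes every player a copy of the macro (redundancy,
#' \eqn{\Psi < 0}), large jitter hides the macro from any single player
#' (synergy, \eqn{\Psi > 0}). See [stationary_psi_com()] for the closed form.
#'
#' In the `ramp_s` seconds before each scheduled shot the shooting team's
#' `sigma_idio` is multiplied per second by `gamma_attack` (compounding) and
#' the conceding team's by `gamma_defend`; with the defaults this drives the
#' attacker towards synergy and the defender towards redundancy. The ramps
#' are knobs of the generator, not claims about real football.
#'
#' @param n_players outfield players per team.
#' @param pitch_length,pitch_width pitch dimensions, metres.
#' @param half_length_s half duration in seconds (frames at 1 Hz).
#' @param half_gap_s clock gap between the two halves, seconds.
#' @param phi_p,phi_n AR(1) persistence of the latent centre in / out of
#'   possession, in `[0, 1)`.
#' @param sigma_macro stationary SD of the latent centre around its attractor,
#'   metres per coordinate.
#' @param rho_idio,sigma_idio AR(1) persistence and stationary SD (metres) of
#'   the per-player idiosyncratic deviation.
#' @param center_idio mean-centre the idiosyncratic deviations across the team
#'   at every second (formation-preserving jitter).
#' @param formation_offsets `n_players` x 2 matrix of fixed player offsets
#'   from the team centre, metres; the default 4-4-2-like layout has zero mean.
#' @param attack_x,defend_x attractor x-coordinate (in the team's attacking
#'   direction) while in / out of possession, metres.
#' @param p_stay per-second possession-retention probability of the symmetric
#'   possession chain, in `(0, 1]`.
#' @param shot_hazard per-second shot probability for the possessing team.
#' @param gamma_attack,gamma_defend per-second multiplicative `sigma_idio`
#'   scaling for the shooting / conceding team over the `ramp_s` seconds
#'   before a shot.
#' @param ramp_s pre-shot ramp duration, seconds.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_players = 10,
                             pitch_length = 105, pitch_width = 68,
                             half_length_s = 2700, half_gap_s = 300,
                             phi_p = 0.88, phi_n = 0.45,
                             sigma_macro = 2,
                             rho_idio = 0.5, sigma_idio = 10,
                             center_idio = TRUE,
                             formation_offsets = NULL,
                             attack_x = 4, defend_x = -4,
                             p_stay = 0.985, shot_hazard = 0.003,
                             gamma_attack = 1.02, gamma_defend = 0.98,
                             ramp_s = 60) {
  if (is.null(formation_offsets)) {
    formation_offsets <- default_formation(n_players)
  }
  formation_offsets <- as.matrix(formation_offsets)
  p <- list(n_players = n_players, pitch_length = pitch_length,
            pitch_width = pitch_width, half_length_s = half_length_s,
            half_gap_s = half_gap_s, phi_p = phi_p, phi_n = phi_n,
            sigma_macro = sigma_macro, rho_idio = rho_idio,
            sigma_idio = sigma_idio, center_idio = center_idio,
            formation_offsets = formation_offsets,
            attack_x = attack_x, defend_x = defend_x,
            p_stay = p_stay, shot_hazard = shot_hazard,
            gamma_attack = gamma_attack, gamma_defend = gamma_defend,
            ramp_s = ramp_s)
  class(p) <- "synthetic_params"
  validate_synthetic_params(p)
  p
}

validate_synthetic_params <- function(p) {
  stopifnot(p$n_players >= 2, p$half_length_s >= 2)
  for (phi in c(p$phi_p, p$phi_n)) {
    if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  }
  if (p$rho_idio < 0 || p$rho_idio >= 1) stop("rho_idio must lie in [0, 1)")
  if (p$sigma_macro < 0 || p$sigma_idio < 0) stop("sigma must be >= 0")
  if (p$p_stay <= 0 || p$p_stay > 1) stop("p_stay must lie in (0, 1]")
  if (p$shot_hazard < 0 || p$shot_hazard > 1) {
    stop("shot_hazard must lie in [0, 1]")
  }
  if (nrow(p$formation_offsets) != p$n_players ||
      ncol(p$formation_offsets) != 2) {
    stop("formation_offsets must be an n_players x 2 matrix")
  }
  invisible(p)
}

# Zero-mean 4-4-2-like formation; rows are players, columns (x, y) metres.
default_formation <- function(n_players = 10) {
  base <- cbind(
    x = c(-12, -12, -12, -12, 2, 2, 2, 2, 20, 20),
    y = c(-15, -5, 5, 15, -15, -5, 5, 15, -8, 8))
  if (n_players == 10) return(base)
  ang <- 2 * pi * (seq_len(n_players) - 1) / n_players
  cbind(x = 14 * cos(ang), y = 14 * sin(ang))
}

#' Generate one synthetic match
#'
#' Draws the possession chain and shot events for two halves, then simulates
#' both teams' trajectories (see [synthetic_params()] for the model). The home
#' team attacks in the `+x` direction, the away team in `-x`. Output is fully
#' reproducible from `seed`; velocities are not generated and should be
#' obtained with [differentiate_positions()].
#'
#' @param params a [synthetic_params()] object.
#' @param seed integer RNG seed.
#' @return list with elements `tracking` ([match_tracking()]) and `events`
#'   ([event_log()]).
#' @export
generate_match <- function(params = synthetic_params(), seed = 1) {
  validate_synthetic_params(params)
  set.seed(seed)
  L <- params$half_length_s
  starts <- c(0, L + params$half_gap_s)
  hb <- data.frame(half = 1:2, start = starts, end = starts + L - 1)
  kickoff1 <- sample(c("home", "away"), 1)
  kickoffs <- c(kickoff1, setdiff(c("home", "away"), kickoff1))

  ev_rows <- list()
  poss_rows <- list()
  frame_rows <- list()
  for (h in 1:2) {
    t0 <- starts[h]
    tt <- seq(t0, t0 + L - 1)
    poss <- simulate_possession(L, params$p_stay, kickoffs[h])
    shots_idx <- which(stats::runif(L) < params$shot_hazard)
    shot_team <- poss[shots_idx]
    shot_t <- tt[shots_idx]
    for (team in c("home", "away")) {
      traj <- generate_team_trajectory(
        params,
        possession = poss == team,
        shot_times_for = shot_t[shot_team == team] - t0 + 1,
        shot_times_against = shot_t[shot_team != team] - t0 + 1,
        attack_dir = if (team == "home") 1 else -1)
      n <- params$n_players
      frame_rows[[length(frame_rows) + 1]] <- data.frame(
        t = rep(tt, each = n),
        team = team,
        player = rep(seq_len(n), L),
        x = as.vector(t(traj$positions[, , 1])),
        y = as.vector(t(traj$positions[, , 2])))
    }
    changes <- c(1, which(poss[-1] != poss[-L]) + 1)
    ev_rows[[length(ev_rows) + 1]] <- rbind(
      data.frame(t = t0, team = NA_character_, event_type = "half_start"),
      data.frame(t = tt[changes], team = poss[changes],
                 event_type = "possession_gain"),
      if (length(shot_t)) data.frame(t = shot_t, team = shot_team,
                                     event_type = "shot"),
      data.frame(t = t0 + L - 1, team = NA_character_,
                 event_type = "half_end"))
    poss_rows[[length(poss_rows) + 1]] <- data.frame(t = tt, team = poss)
  }
  events <- event_log(do.call(rbind, ev_rows),
                      possession = do.call(rbind, poss_rows))
  tracking <- match_tracking(do.call(rbind, frame_rows),
                             pitch_length = params$pitch_length,
                             pitch_width = params$pitch_width,
                             sample_rate_hz = 1, half_bounds = hb,
                             validate = FALSE)
  list(tracking = tracking, events = events)
}

# Internal: symmetric two-state possession chain.
simulate_possession <- function(L, p_stay, start_team) {
  teams <- c("home", "away")
  if (p_stay >= 1) return(rep(start_team, L))
  flips <- stats::runif(L - 1) > p_stay
  state <- cumsum(c(match(start_team, teams) - 1L, flips)) %% 2L
  teams[state + 1L]
}

#' Simulate one team's trajectory
#'
#' The per-team kernel of [generate_match()], exposed for direct use: given a
#' possession indicator sequence and (local, 1-based) shot times it simulates
#' the latent centre and the player positions for one half. Uses the current
#' RNG state unless `seed` is given.
#'
#' @param params a [synthetic_params()] object.
#' @param possession logical vector, one element per second: is this team in
#'   possession?
#' @param shot_times_for,shot_times_against 1-based indices (seconds into the
#'   segment) of shots taken by this team / by the opponent.
#' @param attack_dir `+1` if the team attacks towards `+x`, `-1` otherwise.
#' @param seed optional integer seed.
#' @return list with `centre` (T x 2 latent centre), `positions`
#'   (T x n_players x 2) and `sigma_mult` (per-second idiosyncratic SD
#'   multiplier from the pre-shot ramps).
#' @export
generate_team_trajectory <- function(params, possession,
                                     shot_times_for = integer(0),
                                     shot_times_against = integer(0),
                                     attack_dir = 1, seed = NULL) {
  validate_synthetic_params(params)
  if (!is.null(seed)) set.seed(seed)
  L <- length(possession)
  n <- params$n_players
  phi <- ifelse(possession, params$phi_p, params$phi_n)
  sd_inn <- params$sigma_macro * sqrt(1 - phi^2)
  cx <- attack_dir * ifelse(possession, params$attack_x, params$defend_x)

  centre <- matrix(0, L, 2)
  eps <- matrix(stats::rnorm(2 * L), L, 2)
  centre[1, ] <- c(cx[1], 0) + params$sigma_macro * eps[1, ]
  for (t in 2:L) {
    c_t <- c(cx[t], 0)
    centre[t, ] <- c_t + phi[t] * (centre[t - 1, ] - c_t) +
      sd_inn[t] * eps[t, ]
  }

  mult <- sigma_ramp(L, shot_times_for, params$gamma_attack, params$ramp_s) *
    sigma_ramp(L, shot_times_against, params$gamma_defend, params$ramp_s)

  sigma_t <- params$sigma_idio * mult
  inn_scale <- sigma_t * sqrt(1 - params$rho_idio^2)
  inn_scale[1] <- sigma_t[1]  # stationary start
  E <- matrix(stats::rnorm(L * n * 2), L, n * 2) * inn_scale
  D <- apply(E, 2, function(col) {
    as.numeric(stats::filter(col, params$rho_idio, method = "recursive"))
  })
  D <- array(D, c(L, n, 2))
  if (params$center_idio) {
    for (k in 1:2) D[, , k] <- D[, , k] - rowMeans(D[, , k])
  }
  offsets <- params$formation_offsets
  offsets[, 1] <- attack_dir * offsets[, 1]  # mirror the formation in x
  positions <- array(0, c(L, n, 2))
  for (k in 1:2) {
    positions[, , k] <- centre[, k] +
      matrix(offsets[, k], L, n, byrow = TRUE) + D[, , k]
  }
  list(centre = centre, positions = positions, sigma_mult = mult)
}

# Internal: compounding per-second sigma multiplier in the ramp_s seconds
# before each shot. Overlapping ramps of the same role combine by the most
# advanced ramp position (gamma^max k), not by stacking, so a cluster of
# shots cannot blow the jitter up beyond one full ramp.
sigma_ramp <- function(L, shot_times, gamma, ramp_s) {
  if (gamma == 1 || !length(shot_times)) return(rep(1, L))
  idx <- rep(0L, L)
  for (s in shot_times) {
    k <- seq_len(ramp_s)
    t <- s - ramp_s - 1 + k
    ok <- t >= 1 & t <= L
    idx[t[ok]] <- pmax(idx[t[ok]], k[ok])
  }
  gamma^idx
}

#' Limiting Psi of the AR(1) centre-of-mass model
#'
#' Closed-form limits of the practical causal-emergence criterion for a team
#' whose centre of mass follows a 2-D isotropic AR(1) with persistence `phi`
#' (lag 1, centre-of-mass macro, formation-preserving jitter). In the
#' `sigma_idio -> Inf` limit every player is uninformative about the future
#' macro and \eqn{\Psi \to -\ln(1-\phi^2)} (the macro's own mutual
#' information across one lag, two independent coordinates). In the
#' `sigma_idio -> 0` limit every player duplicates the macro, so the micro sum
#' cancels and overshoots: \eqn{\Psi \to (1-N)\,(-\ln(1-\phi^2))}.
#'
#' @param phi AR(1) persistence in `[0, 1)`; a [synthetic_params()] object is
#'   accepted (its `phi_p` is used).
#' @param n_players number of micro variables N (players).
#' @param limit `"synergy"` (`sigma_idio -> Inf`) or `"redundancy"`
#'   (`sigma_idio -> 0`).
#' @return Psi limit in nats.
#' @seealso [stationary_psi_com()] for the finite-`sigma_idio` value.
#' @export
theoretical_psi_limit <- function(phi, n_players = 10,
                                  limit = c("synergy", "redundancy")) {
  if (inherits(phi, "synthetic_params")) {
    n_players <- phi$n_players
    phi <- phi$phi_p
  }
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  limit <- match.arg(limit)
  macro_mi <- -log(1 - phi^2)
  switch(limit,
         synergy = macro_mi,
         redundancy = (1 - n_players) * macro_mi)
}

#' Stationary Psi of the centre-of-mass feature under the generator
#'
#' Exact population value of \eqn{\Psi} (lag 1, CoM macro, nats) for the
#' generator of [synthetic_params()] with formation-preserving jitter and a
#' fixed possession state. With centre stationary variance
#' \eqn{v = \sigma_{macro}^2} per coordinate and centred jitter variance
#' \eqn{d = \sigma_{idio}^2 (1 - 1/N)}, the centre of mass equals the latent
#' centre, so the macro term is \eqn{-\ln(1-\phi^2)} and each player's
#' squared correlation with the future macro (per coordinate) is
#' \eqn{\phi^2 v / (v + d)}:
#' \deqn{\Psi = -\ln(1-\phi^2) + N \ln\!\big(1 - \phi^2 v/(v+d)\big).}
#' `rho_idio` drops out because only the lagged cross-correlation with the
#' centre matters at order 1. Interpolates between the two
#' [theoretical_psi_limit()] values as `sigma_idio` grows from 0 to infinity.
#'
#' @param phi AR(1) persistence of the centre in `[0, 1)`.
#' @param sigma_macro stationary SD of the centre, metres.
#' @param sigma_idio stationary SD of the per-player jitter, metres.
#' @param n_players number of players N.
#' @return Psi in nats.
#' @export
stationary_psi_com <- function(phi, sigma_macro = 2, sigma_idio = 10,
                               n_players = 10) {
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  v <- sigma_macro^2
  d <- sigma_idio^2 * (1 - 1 / n_players)
  -log(1 - phi^2) + n_players * log(1 - phi^2 * v / (v + d))
}
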