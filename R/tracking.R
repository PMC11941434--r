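#' Match tracking container
#'
#' A `match_tracking` object holds per-second frames of outfield-player
#' positions (and, once computed, velocities) for both teams of one match,
#' together with pitch geometry, the sampling rate, and the half boundaries.
#' Coordinates are pitch-centred: the origin sits at the centre spot, `x` runs
#' along the long axis of the pitch and `y` along the short axis, both in
#' metres, so a player's distance to the field centre is the plain Euclidean
#' norm of the position.
#'
#' @param frames data.frame with columns `t` (seconds), `team` (`"home"` or
#'   `"away"`), `player` (integer 1..10), `x`, `y` (metres) and optionally
#'   `vx`, `vy` (m/s) and `vel_valid` (logical; velocity usable at this frame).
#' @param pitch_length,pitch_width pitch dimensions in metres.
#' @param sample_rate_hz sampling rate of `frames` in Hz.
#' @param half_bounds data.frame with columns `half`, `start`, `end` (seconds,
#'   inclusive). If `NULL`, a single half spanning the observed time range is
#'   assumed.
#' @param validate run [validate_tracking()] on the result.
#' @param margin out-of-pitch tolerance in metres used by validation.
#' @return An object of class `match_tracking`.
#' @seealso [load_tracking()], [differentiate_positions()], [segment_halves()]
#' @export
match_tracking <- function(frames, pitch_length = 105, pitch_width = 68,
                           sample_rate_hz = 1, half_bounds = NULL,
                           validate = TRUE, margin = 5) {
  frames <- as.data.frame(frames)
  needed <- c("t", "team", "player", "x", "y")
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols)) {
    stop("frames is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(frames)) stop("frames must contain at least one row")
  if (is.null(frames$vx)) frames$vx <- NA_real_
  if (is.null(frames$vy)) frames$vy <- NA_real_
  if (is.null(frames$vel_valid)) frames$vel_valid <- !is.na(frames$vx)
  frames <- frames[order(frames$t, frames$team, frames$player), , drop = FALSE]
  rownames(frames) <- NULL
  if (is.null(half_bounds)) {
    half_bounds <- data.frame(half = 1L, start = min(frames$t),
                              end = max(frames$t))
  }
  half_bounds <- as.data.frame(half_bounds)[order(half_bounds$start), ,
                                            drop = FALSE]
  rownames(half_bounds) <- NULL
  x <- structure(list(frames = frames,
                      pitch_length = pitch_length,
                      pitch_width = pitch_width,
                      sample_rate_hz = sample_rate_hz,
                      half_bounds = half_bounds),
                 class = "match_tracking")
  if (validate) validate_tracking(x, margin = margin)
  x
}

#' @export
print.match_tracking <- function(x, ...) {
  cat("<match_tracking>\n")
  cat(sprintf("  frames: %d rows, %d time points at %g Hz\n",
              nrow(x$frames), length(unique(x$frames$t)), x$sample_rate_hz))
  cat(sprintf("  pitch: %g x %g m\n", x$pitch_length, x$pitch_width))
  for (i in seq_len(nrow(x$half_bounds))) {
    cat(sprintf("  half %d: [%g, %g] s\n", x$half_bounds$half[i],
                x$half_bounds$start[i], x$half_bounds$end[i]))
  }
  invisible(x)
}

#' Validate a match_tracking object
#'
#' Checks the structural invariants of the container: exactly 10 players per
#' team in every frame that falls inside a half, strictly increasing times at
#' uniform `1/sample_rate_hz` spacing within each half, positions within the
#' pitch plus `margin`, and (when velocities are present and flagged valid)
#' consistency of velocity with the position finite difference to 1e-9.
#'
#' @param x a `match_tracking` object.
#' @param margin allowed distance outside the pitch boundary, metres.
#' @param check_bounds,check_velocity toggle individual checks.
#' @return `x`, invisibly; errors describe the offending frame.
#' @export
validate_tracking <- function(x, margin = 5, check_bounds = TRUE,
                              check_velocity = TRUE) {
  fr <- x$frames
  hb <- x$half_bounds
  in_half <- half_of_time(fr$t, hb)
  for (h in hb$half) {
    sub <- fr[!is.na(in_half) & in_half == h, , drop = FALSE]
    if (!nrow(sub)) next
    counts <- table(sub$t, sub$team)
    bad <- which(counts != 10, arr.ind = TRUE)
    if (nrow(bad)) {
      t_bad <- rownames(counts)[bad[1, 1]]
      stop(sprintf(
        "frame t=%s (half %d): expected 10 players per team, found %d",
        t_bad, h, counts[bad[1, 1], bad[1, 2]]))
    }
    tt <- sort(unique(sub$t))
    if (length(tt) > 1) {
      dt <- diff(tt)
      step <- 1 / x$sample_rate_hz
      if (any(dt <= 0) || any(abs(dt - step) > 1e-9)) {
        stop(sprintf(
          "half %d: times must be strictly increasing with spacing %g s", h,
          step))
      }
    }
    if (check_bounds) {
      out <- abs(sub$x) > x$pitch_length / 2 + margin |
        abs(sub$y) > x$pitch_width / 2 + margin
      if (any(out)) {
        i <- which(out)[1]
        stop(sprintf(
          "frame t=%g team=%s player=%d: position (%.2f, %.2f) outside pitch + %g m margin",
          sub$t[i], sub$team[i], sub$player[i], sub$x[i], sub$y[i], margin))
      }
    }
    if (check_velocity && any(sub$vel_valid & !is.na(sub$vx))) {
      ord <- order(sub$team, sub$player, sub$t)
      s <- sub[ord, , drop = FALSE]
      grp <- paste(s$team, s$player)
      same <- c(FALSE, grp[-1] == grp[-length(grp)])
      vx_fd <- c(NA, diff(s$x)) * x$sample_rate_hz
      vy_fd <- c(NA, diff(s$y)) * x$sample_rate_hz
      chk <- same & s$vel_valid & !is.na(s$vx)
      if (any(chk)) {
        err <- pmax(abs(s$vx[chk] - vx_fd[chk]), abs(s$vy[chk] - vy_fd[chk]))
        if (any(err > 1e-9)) {
          i <- which(chk)[which(err > 1e-9)[1]]
          stop(sprintf(
            "frame t=%g team=%s player=%d: velocity inconsistent with position difference",
            s$t[i], s$team[i], s$player[i]))
        }
      }
    }
  }
  invisible(x)
}

# Map times to half ids (NA when outside every half).
half_of_time <- function(t, half_bounds) {
  out <- rep(NA_integer_, length(t))
  for (i in seq_len(nrow(half_bounds))) {
    sel <- t >= half_bounds$start[i] & t <= half_bounds$end[i]
    out[sel] <- half_bounds$half[i]
  }
  out
}

#' Read tracking data from CSV
#'
#' Expects the dialect `t,team,player,x,y[,vx,vy]`: `t` in seconds, `team` in
#' `{home, away}`, `player` in 1..10, coordinates in metres (velocities in
#' m/s). Missing velocity columns are tolerated; velocities can be recomputed
#' with [differentiate_positions()].
#'
#' @param path CSV file path.
#' @inheritParams match_tracking
#' @return A validated `match_tracking`.
#' @export
load_tracking <- function(path, pitch_length = 105, pitch_width = 68,
                          sample_rate_hz = 1, half_bounds = NULL, margin = 5) {
  if (!file.exists(path)) stop("tracking file does not exist: ", path)
  fr <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("t", "team", "player", "x", "y")
  if (!all(needed %in% names(fr))) {
    stop("tracking file ", path, " must have header t,team,player,x,y[,vx,vy]")
  }
  for (col in intersect(c("t", "player", "x", "y", "vx", "vy"), names(fr))) {
    v <- fr[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (any(is.na(num) & !is.na(v) & v != "")) {
        line <- which(is.na(num) & !is.na(v))[1] + 1L  # +1 for the header
        stop(sprintf("malformed value in column '%s' at line %d of %s",
                     col, line, path))
      }
      fr[[col]] <- num
    }
  }
  bad_team <- !fr$team %in% c("home", "away")
  if (any(bad_team)) {
    stop(sprintf("malformed team label at line %d of %s (must be home/away)",
                 which(bad_team)[1] + 1L, path))
  }
  match_tracking(fr, pitch_length = pitch_length, pitch_width = pitch_width,
                 sample_rate_hz = sample_rate_hz, half_bounds = half_bounds,
                 margin = margin)
}

#' Write tracking data to CSV
#'
#' Inverse of [load_tracking()]: the written file reloads to an object whose
#' integer fields are bit-identical and whose float fields agree to 1e-9.
#'
#' @param tracking a `match_tracking` object.
#' @param path output file path.
#' @param velocities include `vx,vy` columns when present.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(tracking, path, velocities = TRUE) {
  fr <- tracking$frames
  if (!nrow(fr)) stop("cannot write tracking with an empty frame list")
  cols <- c("t", "team", "player", "x", "y")
  if (velocities && any(!is.na(fr$vx))) cols <- c(cols, "vx", "vy")
  out <- fr[, cols, drop = FALSE]
  for (col in intersect(c("x", "y", "vx", "vy"), names(out))) {
    out[[col]] <- formatC(out[[col]], format = "g", digits = 17)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Downsample tracking data by decimation
#'
#' Keeps every `sample_rate_hz / target_hz`-th frame, restarting the phase at
#' the first frame of each half, and invalidates velocities (they are defined
#' between consecutive retained samples and must be recomputed with
#' [differentiate_positions()]).
#'
#' @param tracking a `match_tracking` object.
#' @param target_hz target rate; must divide `sample_rate_hz`.
#' @return A `match_tracking` at `target_hz`.
#' @export
downsample_tracking <- function(tracking, target_hz) {
  rate <- tracking$sample_rate_hz
  if (target_hz <= 0) stop("target_hz must be positive")
  k <- rate / target_hz
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("sample_rate_hz (%g) is not divisible by target_hz (%g)",
                 rate, target_hz))
  }
  k <- as.integer(round(k))
  if (k == 1L) return(tracking)
  fr <- tracking$frames
  hb <- tracking$half_bounds
  hid <- half_of_time(fr$t, hb)
  keep <- rep(FALSE, nrow(fr))
  for (h in hb$half) {
    sel <- !is.na(hid) & hid == h
    if (!any(sel)) next
    tt <- sort(unique(fr$t[sel]))
    kept_t <- tt[seq(1, length(tt), by = k)]
    keep[sel & fr$t %in% kept_t] <- TRUE
  }
  fr <- fr[keep, , drop = FALSE]
  fr$vx <- NA_real_
  fr$vy <- NA_real_
  fr$vel_valid <- FALSE
  match_tracking(fr, pitch_length = tracking$pitch_length,
                 pitch_width = tracking$pitch_width,
                 sample_rate_hz = target_hz, half_bounds = hb,
                 validate = FALSE)
}

#' Compute velocities by finite differences
#'
#' Sets `vx(t) = (x(t) - x(t-1)) * sample_rate_hz` (likewise `vy`) for every
#' player, differencing strictly within halves: the first frame of each half
#' receives velocity (0, 0) and `vel_valid = FALSE`, and no difference is
#' taken across the inter-half gap.
#'
#' @param tracking a `match_tracking` object with at least 2 frames per half.
#' @return The tracking with `vx`, `vy`, `vel_valid` filled in.
#' @export
differentiate_positions <- function(tracking) {
  fr <- tracking$frames
  hb <- tracking$half_bounds
  hid <- half_of_time(fr$t, hb)
  if (any(is.na(hid))) {
    fr <- fr[!is.na(hid), , drop = FALSE]
    hid <- hid[!is.na(hid)]
  }
  for (h in hb$half) {
    if (length(unique(fr$t[hid == h])) == 1) {
      stop(sprintf("half %d has a single frame; cannot differentiate", h))
    }
  }
  ord <- order(fr$team, fr$player, fr$t)
  s <- fr[ord, , drop = FALSE]
  shid <- hid[ord]
  grp <- paste(s$team, s$player, shid)
  same <- c(FALSE, grp[-1] == grp[-length(grp)])
  vx <- c(0, diff(s$x)) * tracking$sample_rate_hz
  vy <- c(0, diff(s$y)) * tracking$sample_rate_hz
  vx[!same] <- 0
  vy[!same] <- 0
  s$vx <- vx
  s$vy <- vy
  s$vel_valid <- same
  match_tracking(s, pitch_length = tracking$pitch_length,
                 pitch_width = tracking$pitch_width,
                 sample_rate_hz = tracking$sample_rate_hz,
                 half_bounds = hb, validate = FALSE)
}

#' Split tracking into per-half segments
#'
#' Uses the `half_start` / `half_end` events of an [event_log()] to extract
#' one `match_tracking` per half; frames outside every half are dropped.
#'
#' @param tracking a `match_tracking` object.
#' @param events an `event_log` with paired half markers.
#' @return A list of single-half `match_tracking` objects.
#' @export
segment_halves <- function(tracking, events) {
  hb <- half_bounds_from_events(events)
  out <- vector("list", nrow(hb))
  for (i in seq_len(nrow(hb))) {
    sel <- tracking$frames$t >= hb$start[i] & tracking$frames$t <= hb$end[i]
    if (!any(sel)) stop(sprintf("no frames fall inside half %d", hb$half[i]))
    out[[i]] <- match_tracking(
      tracking$frames[sel, , drop = FALSE],
      pitch_length = tracking$pitch_length,
      pitch_width = tracking$pitch_width,
      sample_rate_hz = tracking$sample_rate_hz,
      half_bounds = hb[i, , drop = FALSE], validate = FALSE)
  }
  out
}

#' Remove play affected by red cards
#'
#' Every frame from a `red_card` event time to the end of the half in which it
#' occurred is removed, so that all retained frames have ten outfield players
#' per team. Halves without red cards are untouched; an empty result is
#' allowed (flagged via attribute `excluded_all`).
#'
#' @param tracking a `match_tracking` object.
#' @param events an `event_log`.
#' @return The filtered `match_tracking` (half bounds shortened accordingly).
#' @export
apply_exclusions <- function(tracking, events) {
  reds <- events$events[events$events$event_type == "red_card", , drop = FALSE]
  if (!nrow(reds)) return(tracking)
  hb <- tracking$half_bounds
  fr <- tracking$frames
  keep <- rep(TRUE, nrow(fr))
  for (i in seq_len(nrow(reds))) {
    h <- half_of_time(reds$t[i], hb)
    if (is.na(h)) next
    j <- which(hb$half == h)
    keep[fr$t >= reds$t[i] & fr$t <= hb$end[j]] <- FALSE
    hb$end[j] <- min(hb$end[j], reds$t[i] - 1 / tracking$sample_rate_hz)
  }
  fr <- fr[keep, , drop = FALSE]
  hb <- hb[hb$end >= hb$start, , drop = FALSE]
  if (!nrow(fr)) {
    out <- tracking
    out$frames <- fr
    out$half_bounds <- hb
    attr(out, "excluded_all") <- TRUE
    return(out)
  }
  match_tracking(fr, pitch_length = tracking$pitch_length,
                 pitch_width = tracking$pitch_width,
                 sample_rate_hz = tracking$sample_rate_hz,
                 half_bounds = hb, validate = FALSE)
}

# Internal: one team's frames as dense arrays (times x players x 2).
team_arrays <- function(tracking, team) {
  fr <- tracking$frames[tracking$frames$team == team, , drop = FALSE]
  if (!nrow(fr)) stop("no frames for team ", team)
  fr <- fr[order(fr$t, fr$player), , drop = FALSE]
  times <- sort(unique(fr$t))
  players <- sort(unique(fr$player))
  n_t <- length(times)
  n_p <- length(players)
  if (nrow(fr) != n_t * n_p) {
    stop("irregular player set for team ", team)
  }
  pos <- array(NA_real_, c(n_t, n_p, 2))
  vel <- array(NA_real_, c(n_t, n_p, 2))
  pos[, , 1] <- matrix(fr$x, n_t, n_p, byrow = TRUE)
  pos[, , 2] <- matrix(fr$y, n_t, n_p, byrow = TRUE)
  vel[, , 1] <- matrix(fr$vx, n_t, n_p, byrow = TRUE)
  vel[, , 2] <- matrix(fr$vy, n_t, n_p, byrow = TRUE)
  vel_valid <- matrix(fr$vel_valid, n_t, n_p, byrow = TRUE)
  list(times = times, players = players, pos = pos, vel = vel,
       vel_valid = apply(vel_valid, 1, all))
}
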