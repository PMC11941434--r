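#' Event log container
#'
#' Holds the timestamped match events (half start/end markers, shots,
#' possession gains, red cards, substitutions) and the per-second possession
#' label sequence. When `possession` is not supplied it is derived from the
#' `possession_gain` events: from each gain onward the gaining team is in
#' possession until the next gain or the end of the half.
#'
#' @param events data.frame with columns `t` (seconds), `team` (`"home"`,
#'   `"away"`, or `NA` for team-less markers) and `event_type` in
#'   `{half_start, half_end, shot, possession_gain, red_card, substitution}`.
#' @param possession optional data.frame `t`, `team`: one row per second with
#'   the team in possession.
#' @return An object of class `event_log`.
#' @export
event_log <- function(events, possession = NULL) {
  events <- as.data.frame(events)
  needed <- c("t", "team", "event_type")
  if (!all(needed %in% names(events))) {
    stop("events must have columns t, team, event_type")
  }
  known <- c("half_start", "half_end", "shot", "possession_gain", "red_card",
             "substitution")
  bad <- setdiff(unique(events$event_type), known)
  if (length(bad)) stop("unknown event_type(s): ", paste(bad, collapse = ", "))
  events <- events[order(events$t), , drop = FALSE]
  rownames(events) <- NULL
  hb <- half_bounds_from_events_df(events)
  shots <- events[events$event_type == "shot", , drop = FALSE]
  if (nrow(shots)) {
    h <- half_of_time(shots$t, hb)
    if (any(is.na(h))) {
      stop(sprintf("shot at t=%g falls outside every half",
                   shots$t[which(is.na(h))[1]]))
    }
  }
  if (is.null(possession)) {
    possession <- derive_possession(events, hb)
  } else {
    possession <- as.data.frame(possession)
    if (!all(c("t", "team") %in% names(possession))) {
      stop("possession must have columns t, team")
    }
    possession <- possession[order(possession$t), , drop = FALSE]
    rownames(possession) <- NULL
  }
  structure(list(events = events, possession = possession, half_bounds = hb),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log>\n")
  tab <- table(x$events$event_type)
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  cat(sprintf("  possession labels: %d s\n", nrow(x$possession)))
  invisible(x)
}

# Internal: pair half_start/half_end events into a half table.
half_bounds_from_events_df <- function(events) {
  starts <- events$t[events$event_type == "half_start"]
  ends <- events$t[events$event_type == "half_end"]
  if (length(starts) != length(ends)) {
    stop(sprintf("unmatched half markers: %d half_start vs %d half_end",
                 length(starts), length(ends)))
  }
  if (!length(starts)) stop("event log has no half markers")
  starts <- sort(starts)
  ends <- sort(ends)
  if (any(ends < starts)) stop("half_end precedes its half_start")
  data.frame(half = seq_along(starts), start = starts, end = ends)
}

#' Half boundaries recorded in an event log
#'
#' @param events an `event_log`.
#' @return data.frame with columns `half`, `start`, `end` (seconds).
#' @export
half_bounds_from_events <- function(events) {
  events$half_bounds
}

# Internal: per-second possession labels from possession_gain events.
derive_possession <- function(events, hb) {
  gains <- events[events$event_type == "possession_gain", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hb))) {
    tt <- seq(hb$start[i], hb$end[i])
    lab <- rep(NA_character_, length(tt))
    g <- gains[gains$t >= hb$start[i] & gains$t <= hb$end[i], , drop = FALSE]
    if (nrow(g)) {
      idx <- findInterval(tt, g$t)
      lab[idx > 0] <- g$team[idx[idx > 0]]
    }
    out[[i]] <- data.frame(t = tt, team = lab)
  }
  do.call(rbind, out)
}

#' Read an event log from CSV
#'
#' The event file has header `t,team,event_type`; an optional possession file
#' has header `t,team` with one row per second.
#'
#' @param path event CSV path.
#' @param possession_path optional possession CSV path.
#' @return An `event_log`.
#' @export
load_events <- function(path, possession_path = NULL) {
  if (!file.exists(path)) stop("event file does not exist: ", path)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  ev$team[ev$team %in% c("", "NA")] <- NA_character_
  poss <- NULL
  if (!is.null(possession_path)) {
    poss <- utils::read.csv(possession_path, stringsAsFactors = FALSE)
  }
  event_log(ev, possession = poss)
}

#' Write an event log to CSV
#'
#' @param events an `event_log`.
#' @param path event CSV path.
#' @param possession_path optional path for the per-second possession series.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, possession_path = NULL) {
  utils::write.csv(events$events, path, row.names = FALSE, quote = FALSE)
  if (!is.null(possession_path)) {
    utils::write.csv(events$possession, possession_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
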