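#' Centre of mass of a set of player positions
#'
#' @param positions N x 2 matrix of positions (metres, pitch-centred).
#' @return length-2 vector, the arithmetic mean of the coordinates.
#' @export
center_of_mass <- function(positions) {
  positions <- as_points(positions)
  if (!nrow(positions)) stop("center_of_mass needs at least one player")
  colMeans(positions)
}

#' Relative-distance macroscopic feature
#'
#' One-dimensional macro feature relating the team to the field centre.
#' Variant `"com_to_center"` (default) is the Euclidean distance from the
#' team's centre of mass to the centre spot; variant `"mean_distance"` is the
#' mean over players of each player's distance to the centre spot. The mean
#' distance always dominates the CoM distance (Jensen / triangle inequality).
#'
#' @param positions N x 2 matrix of pitch-centred positions.
#' @param variant `"com_to_center"` or `"mean_distance"`.
#' @return scalar distance in metres.
#' @export
relative_distance_macro <- function(positions,
                                    variant = c("com_to_center",
                                                "mean_distance")) {
  variant <- match.arg(variant)
  positions <- as_points(positions)
  switch(variant,
         com_to_center = sqrt(sum(center_of_mass(positions)^2)),
         mean_distance = mean(micro_center_distances(positions)))
}

#' Per-player distances to the field centre
#'
#' @param positions N x 2 matrix of pitch-centred positions.
#' @return numeric vector of N Euclidean norms (metres).
#' @export
micro_center_distances <- function(positions) {
  positions <- as_points(positions)
  unname(sqrt(rowSums(positions^2)))
}

# Internal: coerce a length-2 vector or N x 2 object to a bare matrix.
as_points <- function(p) {
  out <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  dimnames(out) <- NULL
  out
}

#' Velocity-similarity edge weight
#'
#' Weight between two moving players: `S_u * S_v * (cos(delta_theta) + 1)`,
#' where `S_u`, `S_v` are their speeds and `delta_theta` the difference in
#' movement angle. Large for fast, co-directed players; zero for anti-parallel
#' movement or when either player is stationary (the angle is then undefined
#' but the weight vanishes regardless).
#'
#' @param s_u,s_v speeds in m/s (non-negative).
#' @param delta_theta movement-angle difference in radians.
#' @return edge weight(s), in `[0, 2 * s_u * s_v]`.
#' @export
velocity_edge_weight <- function(s_u, s_v, delta_theta) {
  if (any(s_u < 0) || any(s_v < 0)) stop("speeds must be non-negative")
  w <- s_u * s_v * (cos(delta_theta) + 1)
  w[s_u == 0 | s_v == 0] <- 0
  w
}

#' Inverse-distance edge weight
#'
#' Weight between two players equal to the inverse of their Euclidean
#' distance, capped at `1/eps` for (near-)coincident players.
#'
#' @param p_u,p_v positions, length-2 vectors (metres).
#' @param eps distance floor in metres (default 0.1).
#' @return edge weight in 1/m.
#' @export
inverse_distance_weight <- function(p_u, p_v, eps = 0.1) {
  d <- sqrt(sum((p_u - p_v)^2))
  1 / max(d, eps)
}

#' Build a weighted team graph for one frame
#'
#' Constructs the complete weighted, undirected graph over a team's players
#' at one time point: nodes are players, edge weights come from velocity
#' similarity ([velocity_edge_weight()]) or spatial proximity
#' ([inverse_distance_weight()]). The adjacency indicator is 1 for every pair
#' of distinct players unless a `threshold` is supplied, in which case only
#' edges with weight strictly above it count as present.
#'
#' @param positions N x 2 matrix of positions (metres).
#' @param velocities N x 2 matrix of velocities (m/s); required for
#'   `mode = "velocity"`.
#' @param mode `"inverse_distance"` or `"velocity"`.
#' @param eps distance floor for inverse-distance weights, metres.
#' @param threshold optional adjacency threshold on the weights (off by
#'   default: complete graph).
#' @return list of class `team_graph` with `W` (symmetric weight matrix, zero
#'   diagonal), `A` (0/1 adjacency) and `mode`.
#' @export
build_team_graph <- function(positions, velocities = NULL,
                             mode = c("inverse_distance", "velocity"),
                             eps = 0.1, threshold = NULL) {
  mode <- match.arg(mode)
  positions <- as_points(positions)
  n <- nrow(positions)
  if (mode == "velocity") {
    if (is.null(velocities)) stop("mode = 'velocity' requires velocities")
    velocities <- as_points(velocities)
    if (any(!is.finite(velocities))) {
      stop("velocities contain non-finite values (invalid-velocity frame)")
    }
    s <- sqrt(rowSums(velocities^2))
    # S_u S_v cos(dtheta) is the dot product, so W = V V' + outer(S, S).
    W <- tcrossprod(velocities) + outer(s, s)
    W[s == 0, ] <- 0
    W[, s == 0] <- 0
  } else {
    d <- as.matrix(stats::dist(positions))
    W <- 1 / pmax(d, eps)
    dimnames(W) <- NULL
  }
  diag(W) <- 0
  A <- matrix(1, n, n)
  diag(A) <- 0
  if (!is.null(threshold)) A <- A * (W > threshold)
  structure(list(W = W, A = A, mode = mode), class = "team_graph")
}

#' Weighted clustering coefficient of one node
#'
#' For node `i` with degree `k_i` (number of neighbours under the adjacency),
#' averages the half-sum of its incident edge weights over every ordered pair
#' of distinct neighbours that are themselves connected:
#' `C_i = 1/(k_i (k_i - 1)) * sum_{j,k != i} ((w_ij + w_ik)/2) a_jk`.
#' Under the complete-graph convention `k_i = N - 1` and the expression
#' reduces to the mean incident edge weight. Weights are not normalised.
#'
#' @param graph a `team_graph`.
#' @param i node index.
#' @return clustering coefficient of node `i`.
#' @export
node_clustering <- function(graph, i) {
  W <- graph$W
  A <- graph$A
  n <- nrow(W)
  k_i <- sum(A[i, ])
  if (k_i < 2) stop(sprintf("node %d has degree %d < 2", i, k_i))
  idx <- setdiff(seq_len(n), i)
  Asub <- A[idx, idx, drop = FALSE]
  # sum over ordered pairs (j,k) of (w_ij + w_ik)/2 * a_jk collapses, by
  # symmetry of A, to sum_j w_ij * deg_j(Asub).
  sum(W[i, idx] * rowSums(Asub)) / (k_i * (k_i - 1))
}

#' Team-average clustering coefficient
#'
#' Mean of [node_clustering()] over all players of the team.
#'
#' @param graph a `team_graph` with at least 3 nodes.
#' @return scalar team clustering coefficient.
#' @export
team_clustering <- function(graph) {
  n <- nrow(graph$W)
  if (n < 3) stop("team_clustering needs at least 3 players")
  mean(vapply(seq_len(n), function(i) node_clustering(graph, i), 0))
}

#' Macro/micro feature series for one team and one half
#'
#' Computes, for every second of a (preprocessed, single-half) tracking
#' segment, one macroscopic feature and the per-player microscopic features
#' it supervenes on:
#' \describe{
#'   \item{`com`}{macro = 2-D centre of mass; micro = 2-D player positions.}
#'   \item{`relative_distance`}{macro = CoM-to-centre distance (or mean
#'     player distance, see `variant`); micro = per-player distance to the
#'     field centre.}
#'   \item{`clust_vel`}{macro = team clustering coefficient of the
#'     velocity-similarity graph; micro = 2-D player velocities. Frames with
#'     invalid velocities (each half's first frame) are masked.}
#'   \item{`clust_dist`}{macro = team clustering coefficient of the
#'     inverse-distance graph; micro = 2-D player positions.}
#' }
#' Micro variables are grouped per player (one micro variable per player,
#' scalar or 2-D), matching an order-1 emergence analysis.
#'
#' @param half a single-half `match_tracking`, velocities computed if
#'   `feature_name = "clust_vel"`.
#' @param team `"home"` or `"away"`.
#' @param feature_name one of `"com"`, `"relative_distance"`, `"clust_vel"`,
#'   `"clust_dist"`.
#' @param variant relative-distance variant, see [relative_distance_macro()].
#' @param eps distance floor for inverse-distance weights, metres.
#' @param threshold optional adjacency threshold, see [build_team_graph()].
#' @return list of class `macro_micro_series`: `times`, `macro` (T x d
#'   matrix), `micro` (T x N x d array), `valid` (logical mask), plus labels.
#' @export
compute_feature_series <- function(half, team,
                                   feature_name = c("com",
                                                    "relative_distance",
                                                    "clust_vel",
                                                    "clust_dist"),
                                   variant = c("com_to_center",
                                               "mean_distance"),
                                   eps = 0.1, threshold = NULL) {
  feature_name <- match.arg(feature_name)
  variant <- match.arg(variant)
  if (nrow(half$half_bounds) != 1) {
    stop("compute_feature_series expects a single-half segment; ",
         "use segment_halves() first")
  }
  arr <- team_arrays(half, team)
  n_t <- length(arr$times)
  n_p <- length(arr$players)
  pos <- arr$pos
  valid <- rep(TRUE, n_t)
  if (feature_name == "com") {
    macro <- cbind(rowMeans(pos[, , 1]), rowMeans(pos[, , 2]))
    micro <- pos
  } else if (feature_name == "relative_distance") {
    dists <- sqrt(pos[, , 1]^2 + pos[, , 2]^2)  # T x N
    macro <- switch(variant,
      com_to_center = cbind(sqrt(rowMeans(pos[, , 1])^2 +
                                   rowMeans(pos[, , 2])^2)),
      mean_distance = cbind(rowMeans(dists)))
    micro <- array(dists, c(n_t, n_p, 1))
  } else if (feature_name == "clust_dist") {
    macro <- cbind(clust_series(pos, mode = "inverse_distance", eps = eps,
                                threshold = threshold))
    micro <- pos
  } else {
    if (all(is.na(arr$vel[, , 1]))) {
      stop("clust_vel requires velocities; run differentiate_positions()")
    }
    valid <- arr$vel_valid
    vel <- arr$vel
    vel[is.na(vel)] <- 0
    macro <- cbind(clust_series(vel, mode = "velocity",
                                threshold = threshold))
    micro <- vel
  }
  structure(list(feature_name = feature_name, team = team,
                 times = arr$times, macro = macro, micro = micro,
                 valid = valid, n_players = n_p),
            class = "macro_micro_series")
}

#' @export
print.macro_micro_series <- function(x, ...) {
  cat(sprintf("<macro_micro_series> %s, team %s: %d s, macro dim %d, %d players\n",
              x$feature_name, x$team, length(x$times), ncol(x$macro),
              x$n_players))
  invisible(x)
}

# Internal: per-second team clustering coefficient over a T x N x 2 array.
# With the complete-graph convention the team average reduces to
# sum(W)/(N(N-1)), which vectorises over frames; the thresholded variant
# falls back to per-frame graphs.
clust_series <- function(xyz, mode, eps = 0.1, threshold = NULL) {
  n_t <- dim(xyz)[1]
  n <- dim(xyz)[2]
  if (is.null(threshold)) {
    if (mode == "velocity") {
      sx <- rowSums(xyz[, , 1])
      sy <- rowSums(xyz[, , 2])
      sq <- xyz[, , 1]^2 + xyz[, , 2]^2
      s <- sqrt(sq)
      # sum over ordered pairs u != v of (v_u . v_v + S_u S_v)
      tot <- (sx^2 + sy^2 - rowSums(sq)) + (rowSums(s)^2 - rowSums(sq))
    } else {
      pairs <- utils::combn(n, 2)
      dx <- xyz[, pairs[1, ], 1] - xyz[, pairs[2, ], 1]
      dy <- xyz[, pairs[1, ], 2] - xyz[, pairs[2, ], 2]
      d <- sqrt(dx^2 + dy^2)
      tot <- 2 * rowSums(1 / pmax(d, eps))
    }
    return(tot / (n * (n - 1)))
  }
  vapply(seq_len(n_t), function(t) {
    g <- build_team_graph(xyz[t, , ],
                          velocities = if (mode == "velocity") xyz[t, , ],
                          mode = mode, eps = eps, threshold = threshold)
    team_clustering(g)
  }, 0)
}
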