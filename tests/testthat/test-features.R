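test_that("centre of mass is the coordinate mean", {
  sq <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  expect_equal(unname(center_of_mass(sq)), c(1, 1))
  expect_equal(unname(center_of_mass(c(3, -4))), c(3, -4))
  set.seed(4)
  pts <- matrix(stats::rnorm(20), 10, 2)
  brute <- c(sum(pts[, 1]), sum(pts[, 2])) / 10
  expect_equal(unname(center_of_mass(pts)), brute, tolerance = 1e-12)
  expect_error(center_of_mass(matrix(0, 0, 2)), "at least one")
})

test_that("relative-distance variants behave and order correctly", {
  two <- rbind(c(3, 4), c(-3, -4))
  expect_equal(relative_distance_macro(two, "com_to_center"), 0)
  expect_equal(relative_distance_macro(two, "mean_distance"), 5)
  expect_error(relative_distance_macro(two, "nope"))
  set.seed(5)
  for (i in 1:20) {
    pts <- matrix(stats::rnorm(20, sd = 10), 10, 2)
    expect_gte(relative_distance_macro(pts, "mean_distance"),
               relative_distance_macro(pts, "com_to_center"))
  }
})

test_that("per-player centre distances are Euclidean norms", {
  expect_equal(micro_center_distances(c(0, 0)), 0)
  expect_equal(micro_center_distances(c(3, 4)), 5)
  set.seed(6)
  pts <- matrix(stats::rnorm(14), 7, 2)
  brute <- vapply(1:7, function(i) sqrt(pts[i, 1]^2 + pts[i, 2]^2), 0)
  expect_equal(micro_center_distances(pts), brute, tolerance = 1e-12)
})

test_that("velocity edge weight follows its identities", {
  expect_equal(velocity_edge_weight(1, 1, 0), 2)
  expect_equal(velocity_edge_weight(2, 3, pi), 0, tolerance = 1e-12)
  expect_equal(velocity_edge_weight(1, 2, pi / 2), 2)
  expect_equal(velocity_edge_weight(0, 5, 1.234), 0)
  expect_error(velocity_edge_weight(-1, 1, 0), "non-negative")
  set.seed(7)
  for (i in 1:50) {
    su <- stats::runif(1, 0, 8); sv <- stats::runif(1, 0, 8)
    th <- stats::runif(1, 0, pi)
    w <- velocity_edge_weight(su, sv, th)
    expect_gte(w, 0)
    expect_lte(w, 2 * su * sv + 1e-12)
  }
})

test_that("inverse-distance weight caps only below eps", {
  expect_equal(inverse_distance_weight(c(0, 0), c(2, 0)), 0.5)
  expect_equal(inverse_distance_weight(c(0, 0), c(0, 0.5)), 2)
  expect_equal(inverse_distance_weight(c(1, 1), c(1, 1)), 10)
  expect_equal(inverse_distance_weight(c(0, 0), c(0.05, 0)), 10)
  expect_equal(inverse_distance_weight(c(0, 0), c(0.11, 0)), 1 / 0.11)
})

test_that("team graphs match hand-computed weights", {
  pos <- rbind(c(0, 0), c(2, 0), c(0, 1))
  g <- build_team_graph(pos, mode = "inverse_distance")
  expect_equal(g$W[1, 2], 1 / 2)
  expect_equal(g$W[1, 3], 1)
  expect_equal(g$W[2, 3], 1 / sqrt(5))
  expect_equal(g$W, t(g$W))
  expect_equal(diag(g$W), rep(0, 3))
  expect_equal(g$A, matrix(1, 3, 3) - diag(3))

  vel <- rbind(c(1, 0), c(0, 2), c(-1, 0))
  gv <- build_team_graph(pos, vel, mode = "velocity")
  expect_equal(gv$W[1, 2], velocity_edge_weight(1, 2, pi / 2))
  expect_equal(gv$W[1, 3], velocity_edge_weight(1, 1, pi), tolerance = 1e-12)
  expect_equal(gv$W[2, 3], velocity_edge_weight(2, 1, pi / 2))

  still <- build_team_graph(pos, matrix(0, 3, 2), mode = "velocity")
  expect_true(all(still$W == 0))

  set.seed(8)
  rp <- matrix(stats::rnorm(20, sd = 5), 10, 2)
  rv <- matrix(stats::rnorm(20), 10, 2)
  for (m in c("inverse_distance", "velocity")) {
    gr <- build_team_graph(rp, rv, mode = m)
    expect_equal(gr$W, t(gr$W), tolerance = 1e-12)
    expect_true(all(gr$W >= 0))
  }
})

test_that("clustering matches the brute-force triple loop", {
  # uniform-weight complete graphs return the weight exactly
  g4 <- structure(list(W = 0.5 * (matrix(1, 4, 4) - diag(4)),
                       A = matrix(1, 4, 4) - diag(4), mode = "inverse_distance"),
                  class = "team_graph")
  for (i in 1:4) expect_identical(node_clustering(g4, i), 0.5)
  expect_identical(team_clustering(g4), 0.5)

  set.seed(9)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    W <- matrix(stats::runif(n * n), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    A <- matrix(1, n, n) - diag(n)
    g <- structure(list(W = W, A = A, mode = "inverse_distance"),
                   class = "team_graph")
    for (i in sample(n, 3)) {
      expect_equal(node_clustering(g, i), brute_node_clustering(W, A, i),
                   tolerance = 1e-12)
    }
    expect_equal(team_clustering(g),
                 mean(vapply(seq_len(n), function(i)
                   brute_node_clustering(W, A, i), 0)),
                 tolerance = 1e-12)
  }
})

test_that("thresholded adjacency still matches the brute-force oracle", {
  set.seed(10)
  pos <- matrix(stats::rnorm(20, sd = 8), 10, 2)
  g <- build_team_graph(pos, mode = "inverse_distance", threshold = 0.08)
  expect_true(any(g$A == 0 & (matrix(1, 10, 10) - diag(10)) == 1))
  for (i in 1:10) {
    if (sum(g$A[i, ]) >= 2) {
      expect_equal(node_clustering(g, i),
                   brute_node_clustering(g$W, g$A, i), tolerance = 1e-12)
    }
  }
  iso <- build_team_graph(pos, mode = "inverse_distance", threshold = 1e6)
  expect_error(node_clustering(iso, 1), "degree")
  tiny <- build_team_graph(rbind(c(0, 0), c(1, 0)), mode = "inverse_distance")
  expect_error(team_clustering(tiny), "at least 3")
})

test_that("feature series have the documented shapes and consistency", {
  tr <- differentiate_positions(make_tracking(0:99, jitter = 3))
  ser <- compute_feature_series(tr, "home", "com")
  expect_equal(dim(ser$macro), c(100, 2))
  expect_equal(dim(ser$micro), c(100, 10, 2))
  for (t in c(1, 50, 100)) {
    expect_equal(ser$macro[t, ], colMeans(ser$micro[t, , ]),
                 tolerance = 1e-9)
  }

  rd <- compute_feature_series(tr, "home", "relative_distance")
  expect_equal(dim(rd$macro), c(100, 1))
  expect_equal(dim(rd$micro), c(100, 10, 1))
  expect_equal(rd$macro[7, 1],
               relative_distance_macro(ser$micro[7, , ], "com_to_center"))
  rdm <- compute_feature_series(tr, "home", "relative_distance",
                                variant = "mean_distance")
  expect_equal(rdm$macro[7, 1], mean(micro_center_distances(ser$micro[7, , ])))
})

test_that("clustering series agree with per-frame graphs", {
  tr <- differentiate_positions(make_tracking(0:49, jitter = 3))
  cd <- compute_feature_series(tr, "home", "clust_dist")
  cv <- compute_feature_series(tr, "home", "clust_vel")
  expect_false(cv$valid[1])  # first frame has no velocity
  expect_true(all(cv$valid[-1]))
  for (t in c(2, 25, 50)) {
    gd <- build_team_graph(cd$micro[t, , ], mode = "inverse_distance")
    expect_equal(cd$macro[t, 1], team_clustering(gd), tolerance = 1e-10)
    gv <- build_team_graph(cd$micro[t, , ], cv$micro[t, , ],
                           mode = "velocity")
    expect_equal(cv$macro[t, 1], team_clustering(gv), tolerance = 1e-10)
  }
})

test_that("translation equivariance holds for all features", {
  tr <- differentiate_positions(make_tracking(0:29, jitter = 2))
  shift <- c(5, -3)
  tr2 <- tr
  tr2$frames$x <- tr2$frames$x + shift[1]
  tr2$frames$y <- tr2$frames$y + shift[2]
  com1 <- compute_feature_series(tr, "home", "com")
  com2 <- compute_feature_series(tr2, "home", "com")
  expect_equal(sweep(com2$macro, 2, shift), com1$macro, tolerance = 1e-9)
  for (f in c("clust_dist", "clust_vel")) {
    a <- compute_feature_series(tr, "home", f)
    b <- compute_feature_series(tr2, "home", f)
    expect_equal(a$macro, b$macro, tolerance = 1e-9)
  }
  r1 <- compute_feature_series(tr, "home", "relative_distance")
  r2 <- compute_feature_series(tr2, "home", "relative_distance")
  expect_equal(r2$macro[, 1],
               sqrt(rowSums(sweep(com1$macro, 2, -shift)^2)),
               tolerance = 1e-9)
})
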