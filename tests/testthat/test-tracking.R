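test_that("tracking round-trips through CSV to 1e-9", {
  tr <- make_tracking(0:2, jitter = 0.37)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(tr, path)
  back <- load_tracking(path)
  expect_equal(nrow(back$frames), 3 * 20)
  expect_identical(back$frames$t, tr$frames$t)
  expect_identical(back$frames$player, tr$frames$player)
  expect_equal(back$frames$x, tr$frames$x, tolerance = 1e-9)
  expect_equal(back$frames$y, tr$frames$y, tolerance = 1e-9)
})

test_that("a minimal one-frame match writes 20 data rows plus header", {
  tr <- make_tracking(0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(tr, path)
  expect_length(readLines(path), 21)
})

test_that("loader rejects malformed and invalid files", {
  tr <- make_tracking(0:2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(tr, path)
  lines <- readLines(path)
  lines[5] <- sub("^([0-9]+),", "\\1x,", lines[5])  # corrupt t on line 5
  writeLines(lines, path)
  expect_error(load_tracking(path), "line 5")

  nine <- make_frames(0:2)
  nine <- nine[!(nine$t == 1 & nine$team == "home" & nine$player == 10), ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(nine, path2, row.names = FALSE, quote = FALSE)
  expect_error(load_tracking(path2), "expected 10 players")
})

test_that("writing an empty frame list errors", {
  tr <- make_tracking(0:2)
  tr$frames <- tr$frames[0, ]
  expect_error(write_tracking(tr, tempfile()), "empty")
})

test_that("validation enforces bounds, spacing and velocity consistency", {
  fr <- make_frames(0:2)
  fr$x[1] <- 80  # beyond 105/2 + 5
  expect_error(match_tracking(fr), "outside pitch")
  expect_silent(match_tracking(fr, margin = 40))

  fr2 <- make_frames(c(0, 1, 3))
  expect_error(match_tracking(fr2), "spacing")

  tr <- differentiate_positions(make_tracking(0:3, jitter = 1))
  expect_silent(validate_tracking(tr))
  tr$frames$vx[25] <- tr$frames$vx[25] + 1e-6
  expect_error(validate_tracking(tr), "velocity inconsistent")
})

test_that("downsampling decimates from each half's first frame", {
  tr <- make_tracking(seq(0, 9.96, by = 0.04), sample_rate_hz = 25)
  down <- downsample_tracking(tr, 1)
  expect_equal(sort(unique(down$frames$t)), 0:9)
  expect_equal(down$sample_rate_hz, 1)
  expect_false(any(down$frames$vel_valid))

  expect_identical(downsample_tracking(tr, 25), tr)
  expect_error(downsample_tracking(tr, 2), "not divisible")

  via5 <- downsample_tracking(downsample_tracking(tr, 5), 1)
  expect_equal(via5$frames, down$frames)
})

test_that("finite-difference velocities match hand values and flag half starts", {
  fr <- data.frame(t = rep(0:2, each = 2),
                   team = rep(c("home", "away"), 3),
                   player = 1, x = rep(c(0, 1, 3), each = 2), y = 0)
  tr <- match_tracking(fr, validate = FALSE)
  d <- differentiate_positions(tr)
  home <- d$frames[d$frames$team == "home", ]
  expect_equal(home$vx, c(0, 1, 2))
  expect_equal(home$vel_valid, c(FALSE, TRUE, TRUE))

  still <- differentiate_positions(make_tracking(0:5))
  expect_true(all(still$frames$vx == 0))
})

test_that("differencing never crosses the half boundary", {
  hb <- data.frame(half = 1:2, start = c(0, 20), end = c(5, 25))
  tr <- make_tracking(c(0:5, 20:25), half_bounds = hb, jitter = 2)
  d <- differentiate_positions(tr)
  first_h2 <- d$frames[d$frames$t == 20, ]
  expect_true(all(!first_h2$vel_valid))
  expect_true(all(first_h2$vx == 0))

  single <- make_tracking(c(0:5, 20), half_bounds = hb)
  expect_error(differentiate_positions(single), "single frame")
})

test_that("differentiate-then-integrate recovers positions to 1e-9", {
  set.seed(11)
  fr <- make_frames(0:99, jitter = 0)
  fr$x <- fr$x + ave(stats::rnorm(nrow(fr)), paste(fr$team, fr$player),
                     FUN = cumsum)
  tr <- differentiate_positions(match_tracking(fr, validate = FALSE,
                                               margin = 1e6))
  one <- tr$frames[tr$frames$team == "home" & tr$frames$player == 3, ]
  one <- one[order(one$t), ]
  rebuilt <- one$x[1] + cumsum(c(0, one$vx[-1])) / tr$sample_rate_hz
  expect_equal(rebuilt, one$x, tolerance = 1e-9)
})

test_that("segment_halves extracts exactly the in-half frames", {
  ev <- event_log(data.frame(
    t = c(0, 10, 20, 30), team = NA_character_,
    event_type = c("half_start", "half_end", "half_start", "half_end")))
  tr <- make_tracking(0:30)
  halves <- segment_halves(tr, ev)
  expect_length(halves, 2)
  expect_equal(sort(unique(halves[[1]]$frames$t)), 0:10)
  expect_equal(sort(unique(halves[[2]]$frames$t)), 20:30)
  expect_false(any(vapply(halves, function(h) 15 %in% h$frames$t, TRUE)))

  expect_error(event_log(data.frame(t = c(0, 10, 20),
                                    team = NA_character_,
                                    event_type = c("half_start", "half_end",
                                                   "half_start"))),
               "unmatched half markers")
})

test_that("red-card exclusion removes frames to the end of that half only", {
  hb_ev <- data.frame(t = c(0, 200, 300, 500), team = NA_character_,
                      event_type = c("half_start", "half_end",
                                     "half_start", "half_end"))
  tr <- make_tracking(c(0:200, 300:500),
                      half_bounds = data.frame(half = 1:2, start = c(0, 300),
                                               end = c(200, 500)))
  ev <- event_log(rbind(hb_ev, data.frame(t = 100, team = "home",
                                          event_type = "red_card")))
  cut <- apply_exclusions(tr, ev)
  expect_equal(sort(unique(cut$frames$t)), c(0:99, 300:500))
  expect_equal(cut$half_bounds$end, c(99, 500))

  ev_clean <- event_log(hb_ev)
  expect_identical(apply_exclusions(tr, ev_clean), tr)
})

test_that("possession labels derive from possession_gain events", {
  ev <- event_log(data.frame(
    t = c(0, 0, 50, 99), team = c(NA, "home", "away", NA),
    event_type = c("half_start", "possession_gain", "possession_gain",
                   "half_end")))
  poss <- ev$possession
  expect_equal(nrow(poss), 100)
  expect_true(all(poss$team[poss$t < 50] == "home"))
  expect_true(all(poss$team[poss$t >= 50] == "away"))
  expect_error(event_log(data.frame(t = 500, team = "home",
                                    event_type = "shot")),
               "no half markers")
})
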