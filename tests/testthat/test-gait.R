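simple_events <- function(types, times, side = "left", fps = 1) {
  gait_events(types, side, as.integer(round(times * fps)) + 1L, time = times)
}

test_that("event validation enforces the heel-strike-first cycle structure", {
  ev <- simple_events(c("heel_strike", "toe_off", "heel_strike"), c(0, 4, 6))
  cycles <- validate_events(ev, "left")
  expect_length(cycles, 1L)
  expect_equal(cycles[[1L]]$toe_off$time, 4)
  bad <- simple_events(c("toe_off", "heel_strike", "heel_strike"), c(0, 2, 6))
  expect_error(validate_events(bad, "left"), class = "ordering_error")
  dup <- simple_events(c("heel_strike", "toe_off", "toe_off", "heel_strike"),
                       c(0, 2, 3, 6))
  expect_error(validate_events(dup, "left"), class = "ordering_error")
  full <- simple_events(c("heel_strike", "heel_off", "toe_off",
                          "max_toe_lift", "heel_strike"),
                        c(0, 3, 4, 5, 6))
  cy <- validate_events(full, "left")
  expect_equal(cy[[1L]]$heel_off$time, 3)
  expect_equal(cy[[1L]]$max_toe_lift$time, 5)
})

test_that("the dummy gait fixture reproduces the printed validation values", {
  g <- gen_dummy_gait()
  cy <- compute_cycles(g$elements$leg, g$truth$events, "left")
  expect_equal(cy$stride_length, c(7, 7))
  expect_equal(cy$toe_lift_height, c(0.5, 0.5))
  expect_equal(cy$stance_duration, c(4, 4))
  expect_equal(cy$swing_duration, c(2, 2))
  expect_equal(cy$stride_duration, cy$stance_duration + cy$swing_duration)
  expect_equal(cy$toe_lift_speed, cy$toe_lift_height / cy$toe_lift_duration)
})

test_that("heel-off annotations yield the heel-down duration", {
  e <- make_leg(10L)
  ev <- gait_events(c("heel_strike", "heel_off", "toe_off", "heel_strike"),
                    "left", c(1L, 3L, 5L, 8L), element = e)
  cy <- compute_cycles(e, ev, "left")
  expect_equal(cy$heel_down_duration, 2)
  expect_lte(cy$heel_down_duration, cy$stance_duration)
})

test_that("degenerate in-place strides measure zero length", {
  n <- 10L
  t <- seq_len(n) - 1L
  e <- element("still", list(
    poi_trajectory("heel", t, cbind(x = rep(1, n), y = rep(0, n))),
    poi_trajectory("toe", t, cbind(x = rep(2, n), y = rep(0, n)))))
  ev <- gait_events(c("heel_strike", "toe_off", "heel_strike"),
                    "left", c(1L, 5L, 9L), element = e)
  expect_equal(compute_cycles(e, ev, "left")$stride_length, 0)
})

test_that("step parameters pair contralateral heel strikes", {
  g <- gen_dummy_gait()
  steps <- step_parameters(g$elements$legs, g$truth$events_both)
  expect_equal(unique(steps$step_duration), g$truth$step_duration)
  expect_equal(unique(steps$step_size), g$truth$step_size)
  # left->right and right->left steps tile the stride
  expect_equal(steps$step_duration[1L] + steps$step_duration[2L],
               g$truth$cycles$stride_duration[1L])
  only_left <- g$truth$events
  expect_error(step_parameters(g$elements$legs, only_left),
               class = "validation_error")
})

test_that("gait diagrams intersect stance intervals", {
  ev <- rbind(simple_events(c("heel_strike", "toe_off", "heel_strike"),
                            c(0, 4, 6), "left"),
              simple_events(c("heel_strike", "toe_off", "heel_strike"),
                            c(3, 7, 9), "right"))
  class(ev) <- c("gait_events", "data.frame")
  gd <- gait_diagram(ev)
  expect_equal(gd$left[1L, ], c(0, 4))
  expect_equal(gd$right[1L, ], c(3, 7))
  expect_equal(gd$overlap[1L, ], c(3, 4))
  # disjoint stances: no overlap rows
  ev2 <- rbind(simple_events(c("heel_strike", "toe_off", "heel_strike"),
                             c(0, 2, 8), "left"),
               simple_events(c("heel_strike", "toe_off", "heel_strike"),
                             c(3, 5, 9), "right"))
  class(ev2) <- c("gait_events", "data.frame")
  expect_identical(nrow(gait_diagram(ev2)$overlap), 0L)
})

test_that("bipedal walking keeps each swing inside the other side's stance", {
  g <- gen_dummy_gait()
  gd <- gait_diagram(g$truth$events_both)
  swings <- cbind(gd$left[, 2L],
                  gd$left[, 1L][-1L][seq_len(nrow(gd$left) - 1L)])
  for (i in seq_len(nrow(swings) - 1L)) {
    inside <- any(gd$right[, 1L] <= swings[i, 1L] &
                  gd$right[, 2L] >= swings[i, 2L])
    expect_true(inside)
  }
})

test_that("two-phase cycles split swim strokes at the mid event", {
  ev <- simple_events(c("cycle_entry", "cycle_mid", "cycle_entry",
                        "cycle_mid", "cycle_entry"),
                      c(0, 0.04, 0.14, 0.18, 0.28), side = "none", fps = 100)
  ph <- two_phase_cycles(ev)
  expect_equal(ph$phase1_duration, c(0.04, 0.04))
  expect_equal(ph$phase2_duration, c(0.10, 0.10))
  single <- simple_events(c("cycle_entry"), 0, side = "none")
  expect_identical(nrow(two_phase_cycles(single)), 0L)
  bad <- simple_events(c("cycle_mid", "cycle_entry"), c(0, 1), side = "none")
  expect_error(two_phase_cycles(bad), class = "ordering_error")
  nonalt <- simple_events(c("cycle_entry", "cycle_entry", "cycle_mid"),
                          c(0, 1, 2), side = "none")
  expect_error(two_phase_cycles(nonalt), class = "ordering_error")
})

test_that("stance + swing equals stride on randomized valid event streams", {
  set.seed(5)
  for (rep in 1:10) {
    k <- sample(3:6, 1L)
    hs <- cumsum(c(0, runif(k - 1L, 2, 5)))
    duty <- runif(1L, 0.4, 0.8)
    to <- hs[-k] + duty * diff(hs)
    ord <- order(c(hs, to))
    ev <- gait_events(c(rep("heel_strike", k), rep("toe_off", k - 1L))[ord],
                      "left", seq_len(2L * k - 1L), time = c(hs, to)[ord])
    e <- element("leg", list(
      poi_trajectory("heel", seq_len(2L * k - 1L) - 1L,
                     cbind(x = seq_len(2L * k - 1L), y = 0)),
      poi_trajectory("toe", seq_len(2L * k - 1L) - 1L,
                     cbind(x = seq_len(2L * k - 1L) + 1, y = 0))))
    # remap frames so event frames index into the element
    ev$frame <- seq_len(nrow(ev))
    cy <- compute_cycles(e, ev, "left")
    expect_equal(cy$stance_duration + cy$swing_duration, cy$stride_duration,
                 tolerance = 1e-9)
    expect_true(all(cy$stance_duration > 0 & cy$swing_duration > 0))
  }
})

test_that("stride lengths telescope along a monotonic progression", {
  g <- gen_dummy_gait()
  cy <- compute_cycles(g$elements$leg, g$truth$events, "left")
  hs <- g$truth$events[g$truth$events$type == "heel_strike", ]
  heel_x <- g$elements$leg$pois$heel$coords[hs$frame, "x"]
  expect_equal(sum(cy$stride_length), abs(heel_x[length(heel_x)] - heel_x[1L]))
})

test_that("the heuristic detector recovers the ground-truth events", {
  g <- gen_dummy_gait()
  det <- detect_events_heuristic(g$elements$leg, side = "left")
  truth <- g$truth$events
  for (type in c("heel_strike", "toe_off", "max_toe_lift")) {
    tf <- sort(truth$frame[truth$type == type])
    df <- sort(det$frame[det$type == type])
    expect_length(df, length(tf))
    expect_true(all(abs(df - tf) <= 1L))
  }
  flat <- element("flat", list(
    poi_trajectory("heel", 0:9, cbind(x = 0:9, y = rep(0, 10))),
    poi_trajectory("toe", 0:9, cbind(x = 1:10, y = rep(0, 10)))))
  expect_error(detect_events_heuristic(flat), class = "detection_error")
  expect_error(detect_events_heuristic(g$elements$leg, height_frac = 0),
               class = "detection_error")
})

test_that("gait parameters ignore display normalization (raw coordinates)", {
  g <- gen_dummy_gait()
  cy <- compute_cycles(g$elements$leg, g$truth$events, "left")
  invisible(stick_diagram(g$elements$leg,
                          normalize = list(poi = "heel", axes = "x")))
  cy2 <- compute_cycles(g$elements$leg, g$truth$events, "left")
  expect_equal(cy2, cy)
})

test_that("event files round trip through the annotation CSV format", {
  g <- gen_dummy_gait()
  f <- tempfile(fileext = ".csv")
  write_gait_events(g$truth$events, f)
  back <- read_gait_events(f, element = g$elements$leg)
  expect_equal(as.data.frame(back), as.data.frame(g$truth$events))
})
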