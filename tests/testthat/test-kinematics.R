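test_that("forward differences reproduce linear and parabolic motion", {
  t <- 0:10
  e <- element("poly", list(poi_trajectory("p", t,
                                           cbind(x = 2 * t, y = t^2))))
  k <- kinematics(e)$p
  expect_equal(k$speeds[, "x"], rep(2, 10))
  expect_equal(k$accels[, "x"], rep(0, 9))
  expect_equal(k$speeds[, "y"], 2 * (0:9) + 1)   # (t+1)^2 - t^2
  expect_equal(k$accels[, "y"], rep(2, 9))
  # 3-4-5 step: magnitude from components
  e2 <- element("tri", list(poi_trajectory("p", 0:2,
                                           cbind(x = c(0, 3, 6), y = c(0, 4, 8)))))
  expect_equal(kinematics(e2)$p$speed_mag, c(5, 5))
  expect_error(kinematics(element("short", list(make_poi(n = 2L)))),
               class = "validation_error")
})

test_that("a single perturbed sample touches only adjacent derivatives", {
  t <- 0:10
  clean <- element("c", list(poi_trajectory("p", t, cbind(x = 2 * t, y = t^2))))
  y2 <- t^2; y2[6L] <- 100
  dirty <- element("d", list(poi_trajectory("p", t, cbind(x = 2 * t, y = y2))))
  kc <- kinematics(clean)$p; kd <- kinematics(dirty)$p
  expect_identical(which(kd$speeds[, "y"] != kc$speeds[, "y"]), c(5L, 6L))
  expect_identical(which(kd$accels[, "y"] != kc$accels[, "y"]), 4:6)
  expect_equal(kd$speeds[, "x"], kc$speeds[, "x"])
})

test_that("absolute mode takes componentwise magnitudes", {
  t <- 0:5
  e <- element("osc", list(poi_trajectory("p", t,
                                          cbind(x = c(0, 1, 0, 1, 0, 1),
                                                y = -t))))
  ks <- kinematics(e, absolute = FALSE)$p
  ka <- kinematics(e, absolute = TRUE)$p
  expect_equal(abs(ks$speeds), ka$speeds)
  expect_equal(abs(ks$accels), ka$accels)
  expect_true(all(ka$speed_mag >= 0))
})

test_that("speed and acceleration magnitudes are rigid-motion invariant", {
  set.seed(7)
  t <- seq(0, 2, by = 0.1)
  e <- element("rnd", list(poi_trajectory("p", t,
                                          cbind(x = cumsum(rnorm(21)),
                                                y = cumsum(rnorm(21))))))
  k0 <- kinematics(e)$p
  moved <- rotate_element(shift_element(e, c(5, -2)), 63)
  k1 <- kinematics(moved)$p
  expect_equal(k1$speed_mag, k0$speed_mag, tolerance = 1e-9)
  expect_equal(k1$accel_mag, k0$accel_mag, tolerance = 1e-9)
  expect_equal(k1$path_length, k0$path_length, tolerance = 1e-9)
})

test_that("missing samples blank out the intervals they touch", {
  t <- 0:6
  e <- element("gap", list(poi_trajectory("p", t,
                                          cbind(x = c(0, 1, 2, NA, 4, 5, 6),
                                                y = rep(0, 7)))))
  k <- kinematics(e)$p
  expect_true(all(is.na(k$speeds[3:4, "x"])))
  expect_false(anyNA(k$speeds[c(1, 2, 5, 6), "x"]))
  expect_equal(k$path_length, 4)  # the two broken intervals are excluded
})

test_that("joint angles match the construction and the dot-product oracle", {
  mk <- function(A, B, C) element("ang", list(
    poi_trajectory("A", 0:1, rbind(A, A)),
    poi_trajectory("B", 0:1, rbind(B, B)),
    poi_trajectory("C", 0:1, rbind(C, C))))
  cases <- list(
    list(C = c(1, 1), expected = 90),
    list(C = c(2, 1), expected = 135),
    list(C = c(2, 0), expected = 180),
    list(C = c(0, 0), expected = 0))
  for (cs in cases) {
    e <- mk(c(0, 0), c(1, 0), cs$C)
    th <- joint_angle(e, "A", "B", "C")$values[1L]
    expect_equal(th, cs$expected, tolerance = 1e-9)
    # independent oracle: arccos of the normalised dot product
    u <- c(0, 0) - c(1, 0); v <- cs$C - c(1, 0)
    if (sqrt(sum(v^2)) > 0)
      expect_equal(th, acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi,
                   tolerance = 1e-9)
  }
  rad <- joint_angle(mk(c(0, 0), c(1, 0), c(1, 1)), "A", "B", "C",
                     unit = "radians")
  expect_equal(rad$values[1L], pi / 2, tolerance = 1e-12)
})

test_that("joint angles are invariant under rigid motion and scaling", {
  e <- gen_angle_chain(c(10, 45, 111, 170))$elements$angle_chain
  th0 <- joint_angle(e, "A", "B", "C")$values
  for (v in list(shift_element(e, c(2, 3)), rotate_element(e, 28),
                 scale_element(e, 3.5)))
    expect_equal(joint_angle(v, "A", "B", "C")$values, th0, tolerance = 1e-9)
})

test_that("zero-length segments give missing angles, not errors", {
  e <- element("deg", list(
    poi_trajectory("A", 0:1, cbind(c(0, 0), c(0, 1))),
    poi_trajectory("B", 0:1, cbind(c(0, 1), c(0, 0))),  # frame 1: B == A
    poi_trajectory("C", 0:1, cbind(c(1, 2), c(1, 1)))))
  th <- joint_angle(e, "A", "B", "C")$values
  expect_true(is.na(th[1L]))
  expect_false(is.na(th[2L]))
})

test_that("describe reports the standard statistics with the committed tie rule", {
  d <- describe(c(1, 2, 2, 3))
  expect_equal(d$mean, 2); expect_equal(d$median, 2)
  expect_equal(d$mode, 2); expect_equal(d$min, 1); expect_equal(d$max, 3)
  expect_equal(d$sd, sd(c(1, 2, 2, 3)))
  d1 <- describe(5)
  expect_equal(d1$sd, 0); expect_equal(d1$n, 1L)
  expect_equal(describe(c(1, 1, 2, 2))$mode, 1)   # ties -> smallest
  dt <- describe(c(5, 1, 9), times = c(10, 20, 30))
  expect_equal(dt$t_min, 20); expect_equal(dt$t_max, 30)
  expect_error(describe(c(NA_real_, NA_real_)), class = "validation_error")
})

test_that("stick diagrams anchor the reference POI without moving the data", {
  e <- make_leg()
  sd0 <- stick_diagram(e)
  expect_length(sd0$frames, 10L)
  expect_identical(nrow(sd0$frames[[1L]]), 2L)
  sdn <- stick_diagram(e, normalize = list(poi = "heel", axes = "x"))
  heel_x <- vapply(sdn$frames, function(m) m["heel", "x"], numeric(1))
  expect_equal(heel_x, rep(heel_x[1L], 10L))
  # normalization is display-only: angles recomputed on the raw element
  tri <- gen_angle_chain(c(30, 60))$elements$angle_chain
  before <- joint_angle(tri, "A", "B", "C")$values
  invisible(stick_diagram(tri, normalize = list(poi = "B", axes = c("x", "y"))))
  expect_equal(joint_angle(tri, "A", "B", "C")$values, before)
  expect_error(stick_diagram(element("one", list(make_poi()))),
               class = "validation_error")
})

test_that("occupancy heatmaps conserve counts and honour the extent", {
  p <- poi_trajectory("still", 0:9, cbind(x = rep(2, 10), y = rep(3, 10)))
  h <- occupancy_heatmap(p, 10, 10, extent = c(0, 4, 0, 6))
  expect_equal(sum(h$counts), 10L)
  expect_equal(max(h$counts), 10L)       # all mass in one bin
  # uniform grid-filling fixture: one sample per bin
  g <- expand.grid(x = (seq_len(4) - 0.5) / 4, y = (seq_len(4) - 0.5) / 4)
  pu <- poi_trajectory("grid", seq_len(16) - 1L, cbind(g$x, g$y))
  hu <- occupancy_heatmap(pu, 4, 4, extent = c(0, 1, 0, 1))
  expect_true(all(hu$counts == 1L))
  # missing samples are not binned
  pm <- poi_trajectory("m", 0:4, cbind(c(1, NA, 1, 1, 1), c(1, 2, 1, 1, 1)))
  expect_equal(occupancy_heatmap(pm, 3, 3, extent = c(0, 2, 0, 2))$n_binned, 4L)
  expect_error(occupancy_heatmap(p, 5, 5, extent = c(1, 1, 0, 1)),
               class = "validation_error")
})

test_that("path length sums step displacements", {
  sq <- poi_trajectory("sq", 0:4, cbind(x = c(0, 1, 1, 0, 0),
                                        y = c(0, 0, 1, 1, 0)))
  expect_equal(path_length(sq), 4)
  line <- poi_trajectory("l", 0:2, cbind(x = c(0, 1.5, 3), y = c(0, 2, 4)))
  expect_equal(path_length(line), 5)
  still <- poi_trajectory("s", 0:3, cbind(rep(1, 4), rep(1, 4)))
  expect_equal(path_length(still), 0)
  expect_error(path_length(make_poi(n = 1L)), class = "validation_error")
})
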