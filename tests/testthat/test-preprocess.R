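outlier_element <- function(y = c(1, 2, 100, 4, 5)) {
  element("demo", list(poi_trajectory("p", 0:4, cbind(x = 0:4, y = y))))
}

test_that("MAD outliers are flagged and replaced by each method", {
  res <- replace_outliers(outlier_element(), mad_k = 3, method = "interpolation")
  expect_equal(res$element$pois$p$coords[, "y"], c(1, 2, 3, 4, 5))
  expect_identical(res$report$index, 3L)
  expect_identical(res$report$axis, "y")
  res_prev <- replace_outliers(outlier_element(), method = "previous")
  expect_equal(res_prev$element$pois$p$coords[, "y"], c(1, 2, 2, 4, 5))
  res_near <- replace_outliers(outlier_element(), method = "nearest")
  expect_equal(res_near$element$pois$p$coords[, "y"][3L], 2)
  res_mw <- replace_outliers(outlier_element(), method = "mean_window", w = 5)
  expect_equal(res_mw$element$pois$p$coords[, "y"][3L], mean(c(1, 2, 4, 5)))
  # clean input is an identity with an empty report
  clean <- replace_outliers(outlier_element(c(1, 2, 3, 4, 5)))
  expect_equal(clean$element$pois$p$coords, outlier_element(1:5)$pois$p$coords)
  expect_identical(nrow(clean$report), 0L)
})

test_that("missing samples are treated as outliers for replacement", {
  e <- element("g", list(poi_trajectory("p", 0:4,
                                        cbind(x = 0:4, y = c(1, 2, NA, 4, 5)))))
  res <- replace_outliers(e, method = "interpolation")
  expect_equal(res$element$pois$p$coords[, "y"], c(1, 2, 3, 4, 5))
  expect_false(any(res$element$pois$p$missing))
})

test_that("constant axes are skipped (zero MAD) and interpolation is idempotent", {
  e <- outlier_element(rep(2, 5))
  expect_silent(res <- replace_outliers(e))
  expect_identical(nrow(res$report), 0L)
  once <- replace_outliers(outlier_element(), method = "interpolation")
  twice <- replace_outliers(once$element, method = "interpolation")
  expect_equal(twice$element$pois$p$coords, once$element$pois$p$coords)
  expect_identical(nrow(twice$report), 0L)
})

test_that("smoothing honours window contracts and known values", {
  e <- element("s", list(poi_trajectory("p", 0:2,
                                        cbind(x = rep(1, 3), y = c(0, 3, 0)))))
  for (m in c("moving_mean", "moving_median", "rms")) {
    ec <- element("c", list(poi_trajectory("p", 0:4,
                                           cbind(x = rep(2, 5), y = rep(7, 5)))))
    expect_equal(smooth_element(ec, m, 3)$pois$p$coords,
                 ec$pois$p$coords, tolerance = 1e-12)
  }
  expect_equal(unname(smooth_element(e, "moving_mean", 3)$pois$p$coords[2L, "y"]), 1)
  expect_equal(unname(smooth_element(e, "rms", 3)$pois$p$coords[2L, "y"]), sqrt(3))
  expect_error(smooth_element(e, "moving_mean", 4), class = "validation_error")
  expect_error(smooth_element(e, "moving_mean", 5), class = "validation_error")
})

test_that("axis inversion reflects about the pivot and is an involution", {
  e <- element("i", list(poi_trajectory("p", 0:2,
                                        cbind(x = c(0, 5, 10), y = 1:3))))
  inv <- invert_axis(e, "x")           # default pivot: midpoint 5
  expect_equal(inv$pois$p$coords[, "x"], c(10, 5, 0))
  expect_equal(invert_axis(inv, "x")$pois$p$coords, e$pois$p$coords)
  inv0 <- invert_axis(e, "x", pivot = 0)
  expect_equal(inv0$pois$p$coords[, "x"], c(0, -5, -10))
})

test_that("shift, rotate and scale apply the documented transforms", {
  e <- element("t", list(poi_trajectory("p", 0:1,
                                        cbind(x = c(1, 1), y = c(0, 2)))))
  r <- rotate_element(e, 90, center = c(0, 0))
  expect_equal(r$pois$p$coords[1L, ], c(x = 0, y = 1), tolerance = 1e-12)
  sc <- scale_element(e, 2, center = c(0, 0))
  expect_equal(sc$pois$p$coords[2L, ], c(x = 2, y = 4))
  sh <- shift_element(e, c(3, -1))
  expect_equal(shift_element(sh, c(-3, 1))$pois$p$coords, e$pois$p$coords)
  expect_error(scale_element(e, 0), class = "validation_error")
  # times are never touched by spatial transforms
  expect_identical(r$pois$p$times, e$pois$p$times)
})

test_that("shift/rotate/invert are per-frame isometries", {
  set.seed(42)
  t <- 0:9
  e <- element("iso", list(
    poi_trajectory("a", t, matrix(rnorm(20), 10)),
    poi_trajectory("b", t, matrix(rnorm(20), 10)),
    poi_trajectory("c", t, matrix(rnorm(20), 10))))
  variants <- list(shift_element(e, c(2, -3)),
                   rotate_element(e, 37),
                   invert_axis(e, "y"))
  for (v in variants) for (i in c(1L, 5L, 10L))
    expect_equal(frame_distances(v, i), frame_distances(e, i),
                 tolerance = 1e-12)
})

test_that("every preprocess operation is pure and appends one history entry", {
  e <- make_leg()
  ops <- list(
    function(x) smooth_element(x, "moving_mean", 3),
    function(x) invert_axis(x, "y"),
    function(x) shift_element(x, c(1, 1)),
    function(x) rotate_element(x, 10),
    function(x) scale_element(x, 2),
    function(x) trim_time(x, 1, 8),
    function(x) downsample_view(x, 2),
    function(x) replace_outliers(x)$element)
  for (op in ops) {
    before <- e
    out <- op(e)
    expect_identical(e, before)                     # input untouched
    expect_length(out$history, length(e$history) + 1L)
  }
})

test_that("auto_align recovers a pure translation exactly", {
  e <- make_leg()
  moved <- shift_element(e, c(3, -1))
  aligned <- auto_align(moved, e, "heel", at_time = 4)
  expect_equal(aligned$pois$heel$coords, e$pois$heel$coords, tolerance = 1e-12)
  same <- auto_align(e, e, "toe", at_time = 0)
  expect_equal(same$pois$toe$coords, e$pois$toe$coords)
  expect_error(auto_align(e, e, "hip", 0), class = "validation_error")
})

test_that("trim keeps the closed interval and rejects empty results", {
  e <- make_leg()
  tr <- trim_time(e, 2, 4)
  expect_equal(element_times(tr), c(2, 3, 4))
  expect_equal(trim_time(e, 0, 9)$pois$heel$coords, e$pois$heel$coords)
  expect_error(trim_time(e, 100, 200), class = "validation_error")
  s <- sine_trace(duration = 1)
  expect_equal(range(trim_time(s, 0.25, 0.5)$times), c(0.25, 0.5))
})

test_that("display-only downsampling is tagged and blocked from kinematics", {
  e <- make_leg(100L)
  v <- downsample_view(e, 10)
  expect_length(element_times(v), 10L)
  expect_true(v$display_only)
  expect_error(kinematics(v), class = "contract_error")
  expect_length(element_times(downsample_view(e, 1)), 100L)
})

test_that("stitch rejoins a split element exactly and applies the patch transform", {
  e <- make_leg(20L)
  for (t in c(5, 10.5, 17)) {
    parts <- split_element(e, t)
    re <- stitch_elements(parts$before, parts$after, t)
    expect_equal(re$pois$heel$coords, e$pois$heel$coords)
    expect_equal(element_times(re), element_times(e))
  }
  # patch from a shifted camera, manual offset restores continuity
  parts <- split_element(e, 10)
  moved <- shift_element(parts$after, c(5, 0))
  re <- stitch_elements(parts$before, moved, 10, offset = c(-5, 0))
  expect_equal(re$pois$heel$coords, e$pois$heel$coords, tolerance = 1e-12)
  bad_patch <- element("x", list(parts$after$pois$toe))
  expect_error(stitch_elements(parts$before, bad_patch, 10),
               class = "validation_error")
})
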