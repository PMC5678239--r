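test_that("RGB to HSV conversion follows the standard conventions", {
  p <- rgb_to_hsv_planes(solid_frame(2, 2, c(255, 0, 0)))
  expect_equal(p$hue[1, 1], 0)
  expect_equal(p$saturation[1, 1], 1)
  expect_equal(p$value[1, 1], 1)
  expect_equal(rgb_to_hsv_planes(solid_frame(1, 1, c(0, 255, 0)))$hue[1, 1], 120)
  g <- rgb_to_hsv_planes(solid_frame(1, 1, c(128, 128, 128)))
  expect_equal(g$saturation[1, 1], 0)
  expect_equal(g$hue[1, 1], 0)
})

test_that("hue thresholding gates on circular hue distance and S/V minima", {
  red <- rgb_to_hsv_planes(solid_frame(4, 3, c(255, 0, 0)))
  expect_true(all(threshold_hue(red, 0, 10)$cells))
  blue <- rgb_to_hsv_planes(solid_frame(4, 3, c(0, 0, 255)))
  expect_false(any(threshold_hue(blue, 0, 10)$cells))
  # hue wraps: 355 degrees is 5 degrees from the red center at 0
  wrap <- grDevices::col2rgb(grDevices::hsv(355 / 360, 1, 1))[, 1]
  expect_true(all(threshold_hue(rgb_to_hsv_planes(solid_frame(2, 2, wrap)),
                                0, 10)$cells))
  # saturated-red hue but value below the gate stays black
  dark <- rgb_to_hsv_planes(solid_frame(2, 2, c(50, 0, 0)))
  expect_false(any(threshold_hue(dark, 0, 10, val_min = 0.3)$cells))
  # mask conservation on a mixed frame
  sc <- scene_config(frame_width = 150, frame_height = 60, target_width = 30,
                     target_height = 20, distractor_red_fraction = 0.05,
                     seed = 4)
  m <- threshold_hue(rgb_to_hsv_planes(render_frame(sc, 0)))
  expect_equal(sum(m$cells) + sum(!m$cells), 150 * 60)
})

test_that("strip partition covers every column once, wider strips leftmost", {
  part <- neuroloop:::strip_partition(103)
  expect_length(part, 103)
  widths <- as.vector(table(part))
  expect_equal(widths, c(21, 21, 21, 20, 20))
  # brute-force check on a range of widths
  for (w in c(5, 7, 100, 101, 104)) {
    p <- neuroloop:::strip_partition(w)
    expect_length(p, w)
    expect_true(all(diff(p) %in% c(0, 1)))  # contiguous strips, left to right
    tw <- as.vector(table(p))
    expect_lte(diff(range(tw)), 1)
    expect_true(all(diff(tw) <= 0))  # wider strips leftmost
  }
  expect_error(strip_sums(manual_mask(matrix(TRUE, 3, 4))), "at least 5")
})

test_that("strip sums count white pixels per strip with the middle shared", {
  all_white <- strip_sums(manual_mask(matrix(TRUE, 50, 100)))
  expect_equal(all_white$sums, rep(1000, 5))
  expect_equal(all_white$left3, 3000)
  expect_equal(all_white$right3, 3000)
  one <- matrix(FALSE, 10, 100); one[1, 1] <- TRUE
  expect_equal(strip_sums(manual_mask(one))$sums, c(1, 0, 0, 0, 0))
  # conservation on random masks
  set.seed(11)
  for (i in 1:5) {
    cells <- matrix(stats::runif(40 * 95) < 0.3, 40, 95)
    s <- strip_sums(manual_mask(cells))
    expect_equal(sum(s$sums), sum(cells))
    expect_equal(s$left3 - s$right3, s$sums[1] + s$sums[2] - s$sums[4] - s$sums[5])
  }
})

test_that("stimulus quantization: one signal per 500-pixel imbalance, contralateral", {
  q <- function(sums) do.call(neuroloop:::new_strip_sums, list(sums))
  s1 <- stimulus_from_sums(q(c(500, 0, 0, 0, 0)), 500)
  expect_equal(s1$side, "RIGHT"); expect_equal(s1$count, 1L)
  s2 <- stimulus_from_sums(q(c(0, 0, 0, 1250, 0)), 500)
  expect_equal(s2$side, "LEFT"); expect_equal(s2$count, 2L)
  s3 <- stimulus_from_sums(q(c(100, 100, 999, 100, 100)), 500)
  expect_equal(s3$side, "NONE"); expect_equal(s3$count, 0L)
  # sub-quantum imbalance produces nothing
  expect_equal(stimulus_from_sums(q(c(499, 0, 0, 0, 0)), 500)$side, "NONE")
  expect_error(stimulus_from_sums(q(c(1, 0, 0, 0, 0)), 0), "positive")
})

test_that("mirroring a mask swaps the stimulus side and preserves the count", {
  set.seed(12)
  for (i in 1:10) {
    cells <- matrix(stats::runif(30 * 100) < 0.4, 30, 100)
    s <- stimulus_from_sums(strip_sums(manual_mask(cells)), 100)
    sm <- stimulus_from_sums(strip_sums(manual_mask(cells[, 100:1])), 100)
    expect_equal(sm$count, s$count)
    expect_equal(sm$side,
                 switch(s$side, LEFT = "RIGHT", RIGHT = "LEFT", NONE = "NONE"))
  }
})

test_that("white pixels confined to the middle strip never stimulate", {
  cells <- matrix(FALSE, 40, 100)
  cells[, 41:60] <- TRUE  # strip 3 of 5 over 100 columns
  s <- stimulus_from_sums(strip_sums(manual_mask(cells)), 500)
  expect_equal(s$side, "NONE")
  expect_equal(s$count, 0L)
})
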