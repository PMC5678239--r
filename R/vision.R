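#' Convert an RGB frame to HSV planes
#'
#' Per-pixel RGB to HSV conversion. Hue is reported in degrees in `[0, 360)`;
#' saturation and value are fractions in `[0, 1]`. Achromatic pixels get hue 0
#' with saturation 0.
#'
#' @param frame An `nl_frame` (see [render_frame()]).
#' @return An `nl_hsv`: list of `hue`, `saturation`, `value` matrices plus
#'   `width` and `height`.
#' @export
rgb_to_hsv_planes <- function(frame) {
  stopifnot(inherits(frame, "nl_frame"))
  h <- frame$height; w <- frame$width
  hsv <- grDevices::rgb2hsv(
    r = as.vector(frame$pixels[, , 1]),
    g = as.vector(frame$pixels[, , 2]),
    b = as.vector(frame$pixels[, , 3]),
    maxColorValue = 255)
  structure(list(
    hue = matrix(hsv[1, ] * 360, h, w),
    saturation = matrix(hsv[2, ], h, w),
    value = matrix(hsv[3, ], h, w),
    width = w, height = h), class = "nl_hsv")
}

#' Threshold HSV planes to a binary mask
#'
#' A pixel is white iff its circular hue distance to `hue_center` is at most
#' `hue_tol` degrees AND its saturation and value meet the minimum gates
#' (weakly saturated or dark pixels never count as target, whatever their
#' hue). Hue distance wraps modulo 360, so a center of 0 with tolerance 10
#' admits hue 355.
#'
#' @param planes An `nl_hsv` from [rgb_to_hsv_planes()].
#' @param hue_center Target hue in degrees.
#' @param hue_tol Hue tolerance in degrees (>= 0).
#' @param sat_min,val_min Minimum saturation / value in `[0, 1]`.
#' @return An `nl_mask`: list with `width`, `height` and logical matrix `cells`.
#' @export
threshold_hue <- function(planes, hue_center = 0, hue_tol = 10,
                          sat_min = 0.5, val_min = 0.3) {
  stopifnot(inherits(planes, "nl_hsv"))
  if (hue_tol < 0) stop_cfg("hue_tol must be >= 0")
  if (sat_min < 0 || sat_min > 1 || val_min < 0 || val_min > 1)
    stop_cfg("sat_min and val_min must be in [0, 1]")
  d <- abs((planes$hue - hue_center + 180) %% 360 - 180)
  cells <- d <= hue_tol & planes$saturation >= sat_min & planes$value >= val_min
  structure(list(width = planes$width, height = planes$height, cells = cells),
            class = "nl_mask")
}

# Strip id (1..5) for each of `width` columns. Strips partition the columns;
# widths differ by at most one pixel, with the wider strips leftmost when
# width %% 5 != 0.
strip_partition <- function(width) {
  if (width < 5) stop_cfg("mask width must be at least 5 columns")
  base <- width %/% 5L
  extra <- width %% 5L
  rep.int(1:5, base + as.integer(seq_len(5) <= extra))
}

new_strip_sums <- function(sums) {
  sums <- as.numeric(sums)
  structure(list(sums = sums,
                 left3 = sum(sums[1:3]),
                 right3 = sum(sums[3:5])),
            class = "nl_strip_sums")
}

#' White-pixel sums over five vertical strips
#'
#' Partitions the mask columns into five vertical strips and counts white
#' pixels per strip. `left3` is the total over the leftmost three strips and
#' `right3` over the rightmost three; the middle strip belongs to both, so it
#' cancels in the difference `left3 - right3`.
#'
#' @param mask An `nl_mask` from [threshold_hue()].
#' @return An `nl_strip_sums`: list with `sums` (5 counts, leftmost first),
#'   `left3` and `right3`.
#' @export
strip_sums <- function(mask) {
  stopifnot(inherits(mask, "nl_mask"))
  strip_sums_from_columns(colSums(mask$cells))
}

# Shared by strip_sums() and the exact fast path in the loop.
strip_sums_from_columns <- function(col_white) {
  part <- strip_partition(length(col_white))
  sums <- vapply(1:5, function(s) sum(col_white[part == s]), numeric(1))
  new_strip_sums(sums)
}

#' Quantize the strip imbalance into a stimulation batch
#'
#' Each full quantum of `Q` white pixels by which the leftmost-3-strip sum
#' exceeds the rightmost-3-strip sum is translated into one digitized synaptic
#' signal delivered to the RIGHT network hemisphere (contralateral wiring), and
#' vice versa. Imbalances below one quantum produce no stimulation.
#'
#' @param sums An `nl_strip_sums` from [strip_sums()].
#' @param quantum Pixel quantum Q per synaptic signal (> 0). Default 500.
#' @return An `nl_stimulus`: list with `side` (`"LEFT"`, `"RIGHT"` or
#'   `"NONE"`) and non-negative integer `count`; `side` is `"NONE"` iff
#'   `count` is 0.
#' @export
stimulus_from_sums <- function(sums, quantum = 500) {
  stopifnot(inherits(sums, "nl_strip_sums"))
  if (quantum <= 0) stop_cfg("quantum must be positive")
  diff <- sums$left3 - sums$right3
  if (diff >= quantum) {
    side <- "RIGHT"; count <- as.integer(diff %/% quantum)
  } else if (-diff >= quantum) {
    side <- "LEFT"; count <- as.integer((-diff) %/% quantum)
  } else {
    side <- "NONE"; count <- 0L
  }
  structure(list(side = side, count = count), class = "nl_stimulus")
}

#' Run the full vision stage on one frame
#'
#' Convenience chain: HSV conversion, hue thresholding, strip sums,
#' stimulus quantization.
#'
#' @inheritParams threshold_hue
#' @inheritParams stimulus_from_sums
#' @param frame An `nl_frame`.
#' @return List with `mask`, `sums`, `stimulus` and `white_count`.
#' @export
frame_to_stimulus <- function(frame, hue_center = 0, hue_tol = 10,
                              sat_min = 0.5, val_min = 0.3, quantum = 500) {
  mask <- threshold_hue(rgb_to_hsv_planes(frame), hue_center, hue_tol,
                        sat_min, val_min)
  sums <- strip_sums(mask)
  list(mask = mask, sums = sums,
       stimulus = stimulus_from_sums(sums, quantum),
       white_count = sum(sums$sums))
}

#' Write a binary mask as PNG
#'
#' @param mask An `nl_mask`.
#' @param path File path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "nl_mask"))
  png::writePNG(mask$cells * 1, target = path)
  invisible(path)
}

#' Write per-frame stimulus records as CSV
#'
#' Expects a data frame with one row per frame, as produced by [run_loop()]
#' (`$stimuli`): `frame`, `t`, `s1..s5`, `left3`, `right3`, `side`, `count`.
#'
#' @param records Data frame of per-frame records.
#' @param path File path.
#' @export
write_stimulus_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
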