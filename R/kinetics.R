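#' Normalize an aggregation curve to the unit interval
#'
#' Min-max scaling `(x - min) / (max - min)`: the signal as a fraction of
#' its total dynamic range, so traces from dyes of very different brightness
#' can be overlaid. Constant curves have no defined normalization and raise.
#'
#' @param read a [kinetic_read()]
#' @param smooth apply a moving-median pre-filter (window 3) before scaling;
#'   off by default
#' @return list of class `normalized_kinetic`: `times_h`, `fraction` in
#'   [0, 1], `source` (the input read)
#' @export
normalize_kinetic <- function(read, smooth = FALSE) {
  if (length(read$rfu) < 2L) {
    stop("normalize_kinetic: need at least two timepoints", call. = FALSE)
  }
  y <- read$rfu
  if (smooth) y <- stats::runmed(y, 3L)
  rng <- range(y)
  if (rng[1L] == rng[2L]) {
    stop_fmt("normalize_kinetic: curve (%s, %s) is constant; normalization undefined",
             read$dye_id, read$condition_id)
  }
  structure(list(times_h = read$times_h,
                 fraction = (y - rng[1L]) / (rng[2L] - rng[1L]),
                 source = read),
            class = "normalized_kinetic")
}

#' Half-maximal time of a normalized aggregation curve
#'
#' The first upward crossing of 0.5, linearly interpolated between the
#' bracketing timepoints. A proxy for aggregation timing that supports
#' early/late comparisons against a reference reporter such as ThT.
#'
#' @param curve a [normalize_kinetic()] result
#' @return t50 in hours
#' @export
half_time <- function(curve) {
  y <- curve$fraction; t <- curve$times_h
  if (y[1L] >= 0.5) return(t[1L])
  above <- which(y >= 0.5)
  if (!length(above)) {
    stop("half_time: curve never reaches 0.5; no half-time defined", call. = FALSE)
  }
  i <- above[1L]
  # linear interpolation on the bracketing segment
  t[i - 1L] + (0.5 - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
}

#' Compare a dye's aggregation timing against a reference
#'
#' Classifies the dye as reporting early, concurrent, or late relative to
#' the reference half-time, with an explicit tolerance: differences within
#' `delta_h` hours are called concurrent.
#'
#' @param dye_t50 dye half-time (hours)
#' @param reference_t50 reference (e.g. ThT) half-time (hours)
#' @param delta_h tolerance in hours (default 2)
#' @return list of class `timing_call`: `t50_h`, `relation_to_reference`
#'   (`"early"`, `"concurrent"`, `"late"`), `delta_used_h`
#' @export
compare_timing <- function(dye_t50, reference_t50, delta_h = 2) {
  relation <- if (dye_t50 < reference_t50 - delta_h) "early"
  else if (dye_t50 > reference_t50 + delta_h) "late"
  else "concurrent"
  structure(list(t50_h = dye_t50, relation_to_reference = relation,
                 delta_used_h = delta_h),
            class = "timing_call")
}
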