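# Three-way promoter classification (H3K4me3-Low / H3K4me3-Only /
# bivalent) by quartile thresholds on mark intensities.

#' Classifier parameters
#'
#' @param low_quantile fraction defining the H3K4me3 threshold
#'   (default 0.25, the first quartile Q1).
#' @param high_quantile fraction defining the H3K27me3 threshold
#'   (default 0.75, the third quartile Q3).
#' @return Validated list of class `classifier_params`.
#' @export
classifier_params <- function(low_quantile = 0.25, high_quantile = 0.75) {
  stopifnot(low_quantile > 0, high_quantile < 1,
            low_quantile < high_quantile)
  structure(list(low_quantile = low_quantile, high_quantile = high_quantile),
            class = "classifier_params")
}

#' Linear-interpolation sample quantile
#'
#' The classical interpolated quantile: with sorted values
#' `x_(1) <= ... <= x_(N)` and position `h = 1 + (N - 1) q`, returns
#' `x_(floor(h)) + (h - floor(h)) (x_(ceiling(h)) - x_(floor(h)))`
#' (i.e. `stats::quantile` type 7, R's default).
#'
#' @param values non-empty numeric vector.
#' @param q quantile fraction in `[0, 1]` (vectorized).
#' @return Quantile value(s).
#' @export
interp_quantile <- function(values, q) {
  if (length(values) == 0) stop("quantile of empty vector", call. = FALSE)
  stopifnot(all(q >= 0 & q <= 1), !anyNA(values))
  unname(stats::quantile(values, q, type = 7, names = FALSE))
}

#' Classify promoters by H3K4me3/H3K27me3 quartile thresholds
#'
#' Two sequential cuts: promoters whose H3K4me3 intensity is strictly
#' below the Q1 of H3K4me3 over the whole catalog are `H3K4me3_LOW`;
#' among the remaining (H3K4me3-High) promoters, those whose H3K27me3
#' intensity is strictly above the Q3 of H3K27me3 over the *whole*
#' catalog are `BIVALENT`, the rest `H3K4me3_ONLY`.  Both thresholds are
#' computed over the full catalog, so the bivalent count is generally
#' not 25% of the High subset.  The rule depends only on ranks, and with
#' N = 23,927 distinct H3K4me3 values labels exactly 5,982 promoters
#' Low (the Q1 position 5,982.5 falls strictly between the 5,982nd and
#' 5,983rd order statistics).
#'
#' @param h3k4me3,h3k27me3 per-promoter mean window intensities, aligned
#'   to the same promoter catalog (equal lengths).
#' @param params a [classifier_params()].
#' @return Factor with levels `H3K4me3_LOW`, `H3K4me3_ONLY`, `BIVALENT`,
#'   with attributes `t_low` and `t_high` holding the thresholds used.
#' @export
classify_promoters <- function(h3k4me3, h3k27me3,
                               params = classifier_params()) {
  if (length(h3k4me3) != length(h3k27me3)) {
    stop("intensity vectors must align to the same promoter catalog",
         call. = FALSE)
  }
  if (length(h3k4me3) == 0) {
    return(factor(character(), levels = c("H3K4me3_LOW", "H3K4me3_ONLY",
                                          "BIVALENT")))
  }
  t_low <- interp_quantile(h3k4me3, params$low_quantile)
  t_high <- interp_quantile(h3k27me3, params$high_quantile)
  lab <- ifelse(h3k4me3 < t_low, "H3K4me3_LOW",
                ifelse(h3k27me3 > t_high, "BIVALENT", "H3K4me3_ONLY"))
  out <- factor(lab, levels = c("H3K4me3_LOW", "H3K4me3_ONLY", "BIVALENT"))
  attr(out, "t_low") <- t_low
  attr(out, "t_high") <- t_high
  out
}

#' Per-window mark intensities with replicate averaging
#'
#' Quantifies one or more replicate tracks over promoter windows and
#' averages the per-window intensities after normalizing each track to
#' a common mass; averaging replicate windows (rather than pooling raw
#' tracks) is symmetric and scale-stable.
#'
#' @param tracks a [signal_track()] or list of replicate tracks.
#' @param windows interval data.frame (e.g. promoter windows).
#' @param target_mass per-track normalization mass (default 1e6).
#' @return Numeric vector of mean intensities, one per window.
#' @export
mark_intensity <- function(tracks, windows, target_mass = 1e6) {
  if (inherits(tracks, "signal_track")) tracks <- list(tracks)
  mats <- vapply(tracks, function(tr) {
    window_intensity(normalize_track(tr, target_mass), windows)
  }, numeric(nrow(windows)))
  if (nrow(windows) == 1) mats <- matrix(mats, nrow = 1)
  rowMeans(mats)
}
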