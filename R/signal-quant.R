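# Windowed intensity quantification over coverage tracks, binned
# metaprofile matrices, and log2 differential intensity.

# Cumulative-mass representation of one chromosome's runs: F(x) = signal
# mass in [0, x).  Piecewise linear, exact for fractional bin overlaps.
track_cumfun <- function(runs) {
  s <- runs$start; e <- runs$end; v <- runs$value
  cum <- c(0, cumsum(v * (e - s)))
  function(x) {
    i <- findInterval(x, s)
    out <- numeric(length(x))
    pos <- i > 0
    ii <- i[pos]
    out[pos] <- cum[ii] + v[ii] * pmin(pmax(x[pos] - s[ii], 0), e[ii] - s[ii])
    out
  }
}

#' Mean signal density over intervals
#'
#' Exact mean per-base signal of a track inside each interval:
#' `sum(value x overlap length) / interval length`.  Uncovered bases
#' count as 0; a run boundary inside an interval contributes its exact
#' fractional overlap.
#'
#' @param track a [signal_track()].
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); a single interval is also accepted.
#' @return Numeric vector of mean densities, one per interval.
#' @export
window_intensity <- function(track, intervals) {
  validate_intervals(intervals, "query")
  n <- nrow(intervals)
  if (n == 0) return(numeric())
  out <- numeric(n)
  for (ch in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == ch)
    runs <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(runs) == 0) next
    Fm <- track_cumfun(runs)
    mass <- Fm(intervals$end[qi]) - Fm(intervals$start[qi])
    out[qi] <- mass / (intervals$end[qi] - intervals$start[qi])
  }
  out
}

#' Binned intensity matrix around anchors
#'
#' The bwtool-matrix analogue: for each anchor point the flanking
#' `[-flank_bp, +flank_bp)` span is cut into left-closed bins of
#' `bin_bp` and each cell holds the mean signal density in its bin.
#' Rows of minus-strand anchors are reversed so that column order is
#' transcription-oriented (column 1 = most upstream).
#'
#' @param track a [signal_track()].
#' @param anchors data.frame with `chrom`, `pos` (anchor base, e.g. a
#'   TSS), optional `strand` (default `+`) and `name` columns.
#' @param flank_bp half-width of the profiled span; must be divisible by
#'   `bin_bp`.
#' @param bin_bp bin width in bp (default 50).
#' @return Numeric matrix (anchors x bins) with an `"aggregate"`
#'   attribute holding the column-mean profile.
#' @export
profile_matrix <- function(track, anchors, flank_bp = 2000, bin_bp = 50) {
  stopifnot(flank_bp > 0, bin_bp > 0)
  if (flank_bp %% bin_bp != 0) {
    stop("flank_bp must be divisible by bin_bp", call. = FALSE)
  }
  nb <- 2L * as.integer(flank_bp / bin_bp)
  n <- nrow(anchors)
  if (n == 0) {
    m <- matrix(numeric(), 0, nb)
    attr(m, "aggregate") <- rep(NA_real_, nb)
    return(m)
  }
  strand <- if ("strand" %in% names(anchors)) anchors$strand else rep("+", n)
  offs <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  grid <- data.frame(
    chrom = rep(anchors$chrom, each = nb),
    start = rep(anchors$pos, each = nb) + rep(offs, n),
    stringsAsFactors = FALSE
  )
  grid$end <- grid$start + bin_bp
  neg <- grid$start < 0   # off-chromosome bins report 0 signal
  grid$start[neg] <- 0; grid$end[neg] <- bin_bp
  vals <- window_intensity(track, grid)
  vals[neg] <- 0
  m <- matrix(vals, nrow = n, ncol = nb, byrow = TRUE)
  flip <- strand == "-"
  if (any(flip)) m[flip, ] <- m[flip, nb:1, drop = FALSE]
  rownames(m) <- if ("name" %in% names(anchors)) anchors$name else NULL
  attr(m, "aggregate") <- colMeans(m)
  m
}

#' Differential-intensity parameters
#'
#' @param pseudocount symmetric pseudocount added to both terms of a
#'   ratio to stabilize zero-coverage windows (default 0.25).
#' @param fold_threshold linear fold-change threshold (> 1) separating
#'   changed from unchanged signal (default 1.5).
#' @return A validated list of class `diff_params`.
#' @export
diff_params <- function(pseudocount = 0.25, fold_threshold = 1.5) {
  stopifnot(pseudocount >= 0, fold_threshold > 1)
  structure(list(pseudocount = pseudocount, fold_threshold = fold_threshold),
            class = "diff_params")
}

#' Pseudocounted log2 ratio
#'
#' `log2((a + eps) / (b + eps))` with the symmetric pseudocount `eps`
#' from `params`; antisymmetric in its arguments.
#'
#' @param a,b non-negative intensities (vectorized).
#' @param params a [diff_params()].
#' @return log2 ratio(s).
#' @export
log2_ratio <- function(a, b, params = diff_params()) {
  stopifnot(all(a >= 0), all(b >= 0))
  eps <- params$pseudocount
  if (eps == 0 && any(a == 0 & b == 0)) {
    stop("log2 ratio undefined: both intensities zero with zero pseudocount",
         call. = FALSE)
  }
  log2((a + eps) / (b + eps))
}
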