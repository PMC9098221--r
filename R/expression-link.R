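# DEG thresholding on consumed expression tables, peak-to-DEG-TSS
# linkage, mean differential statistics and Wilcoxon rank tests.

#' Read an expression table
#'
#' Tab-delimited with header: `gene`, `value_ctrl`, `value_kd`,
#' `fold_change` (linear KD/control ratio), `p_value`.  The differential
#' model that produced the table is consumed, never recomputed.
#'
#' @param path path to the table.
#' @return data.frame with the five columns above.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "value_ctrl", "value_kd", "fold_change", "p_value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("expression table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(df$p_value < 0 | df$p_value > 1, na.rm = TRUE)) {
    stop("p_value outside [0, 1]", call. = FALSE)
  }
  if (any(df$fold_change < 0, na.rm = TRUE)) {
    stop("fold_change must be a non-negative ratio", call. = FALSE)
  }
  df
}

#' Call differential expression direction
#'
#' The printed thresholding rule with inclusive boundaries: `UP` when
#' `p <= p_max` and `fold_change >= fc_min`; `DOWN` when `p <= p_max`
#' and `fold_change <= 1/fc_min`; otherwise `NONE`.  Replacing the fold
#' change by its reciprocal flips UP and DOWN.
#'
#' @param records expression data.frame ([read_expression_table()]).
#' @param p_max p-value cutoff (default 0.05, inclusive).
#' @param fc_min linear fold-change cutoff (default 1.5, inclusive).
#' @return Factor with levels `UP`, `DOWN`, `NONE`, aligned to
#'   `records`.
#' @export
filter_degs <- function(records, p_max = 0.05, fc_min = 1.5) {
  stopifnot(fc_min > 1, p_max > 0)
  sig <- records$p_value <= p_max
  lab <- ifelse(sig & records$fold_change >= fc_min, "UP",
                ifelse(sig & records$fold_change <= 1 / fc_min, "DOWN",
                       "NONE"))
  factor(lab, levels = c("UP", "DOWN", "NONE"))
}

# Closest peak (edge distance <= max_dist) to each TSS row.  Ties are
# broken toward the transcription-upstream peak, then by position.
closest_peak_to_tss <- function(tss, peaks, max_dist) {
  n <- nrow(tss)
  out <- data.frame(peak = rep(NA_character_, n),
                    distance = rep(NA_real_, n), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0 || n == 0) return(out)
  for (i in seq_len(n)) {
    pi <- which(peaks$chrom == tss$chrom[i])
    if (!length(pi)) next
    p <- peaks[pi, , drop = FALSE]
    # edge distance of point tss to [start, end): 0 when inside
    d <- pmax(p$start - tss$tss[i], tss$tss[i] - (p$end - 1), 0)
    ok <- d <= max_dist
    if (!any(ok)) next
    p <- p[ok, , drop = FALSE]; d <- d[ok]
    # transcription-upstream: smaller coordinate on +, larger on -
    mid <- (p$start + p$end) / 2
    upstream_first <- if (tss$strand[i] == "-") -mid else mid
    sel <- order(d, upstream_first, p$name)[1]
    out$peak[i] <- p$name[sel]
    out$distance[i] <- d[sel]
  }
  out
}

#' Link occupancy and accessibility peaks to DEG TSSs
#'
#' For each TSS, finds the single closest remodeler (e.g. BRG1) peak
#' within `brg1_max_dist` and the single closest accessibility (ATAC)
#' peak within `atac_max_dist`; either link may be absent.  Equidistant
#' ties resolve toward the transcription-upstream peak, then by
#' position, so linkage is deterministic and per-TSS independent.
#'
#' @param deg_tss data.frame with `name`, `chrom`, `tss`, `strand`
#'   (catalog rows of the DEGs of interest).
#' @param brg1_peaks,atac_peaks peak data.frames.
#' @param brg1_max_dist,atac_max_dist inclusive edge-distance cutoffs in
#'   bp (defaults 2000 and 500).
#' @return `deg_tss` with added columns `brg1_peak`, `brg1_distance`,
#'   `atac_peak`, `atac_distance` (NA when no peak is in range).
#' @export
link_peaks_to_deg_tss <- function(deg_tss, brg1_peaks, atac_peaks,
                                  brg1_max_dist = 2000,
                                  atac_max_dist = 500) {
  b <- closest_peak_to_tss(deg_tss, brg1_peaks, brg1_max_dist)
  a <- closest_peak_to_tss(deg_tss, atac_peaks, atac_max_dist)
  out <- deg_tss
  out$brg1_peak <- b$peak
  out$brg1_distance <- b$distance
  out$atac_peak <- a$peak
  out$atac_distance <- a$distance
  out
}

#' Mean differential intensity over a peak set
#'
#' Per-peak pseudocounted `log2(kd / control)` of the mean window
#' intensity over each peak interval, then the arithmetic mean.  Tracks
#' should be normalized to equal mass first.
#'
#' @param peaks peak data.frame (e.g. the linked peaks of down-regulated
#'   DEGs).
#' @param control_track,kd_track [signal_track()]s.
#' @param params a [diff_params()].
#' @return List with `mean_log2fc` and the per-peak `log2fc` vector.
#' @export
mean_differential <- function(peaks, control_track, kd_track,
                              params = diff_params()) {
  if (nrow(peaks) == 0) {
    stop("mean differential undefined for an empty peak set", call. = FALSE)
  }
  ctrl <- window_intensity(control_track, peaks)
  kd <- window_intensity(kd_track, peaks)
  lfc <- log2_ratio(kd, ctrl, params)
  list(mean_log2fc = mean(lfc), log2fc = lfc)
}

#' Two-sided Wilcoxon rank test
#'
#' Rank-sum (unpaired) or signed-rank (paired) test: exact enumeration
#' when each sample has at most 10 observations and there are no ties
#' (no zero differences, for the paired test), normal approximation
#' with continuity correction otherwise.
#'
#' @param sample_a,sample_b numeric samples; `paired = TRUE` requires
#'   equal lengths.
#' @param paired logical.
#' @return Two-sided p-value.
#' @export
rank_tests <- function(sample_a, sample_b, paired = FALSE) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  if (paired) {
    if (length(sample_a) != length(sample_b)) {
      stop("paired test requires equal-length samples", call. = FALSE)
    }
    if (all(sample_a - sample_b == 0)) {
      stop("degenerate paired test: all differences are zero", call. = FALSE)
    }
  }
  exact <- max(length(sample_a), length(sample_b)) <= 10
  res <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, paired = paired,
                       alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  unname(res$p.value)
}
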