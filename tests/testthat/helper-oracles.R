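# Independent brute-force oracles and tiny fixture builders shared by
# the test files.  Oracles deliberately avoid the package's own
# algorithms: dense per-base expansion, all-pairs scans, and the
# textbook quantile formula.

make_track <- function(chrom, start, end, value) {
  signal_track(data.frame(chrom = chrom, start = start, end = end,
                          value = value, stringsAsFactors = FALSE))
}

make_peaks <- function(chrom, start, end, name = NULL, score = NA_real_) {
  if (is.null(name)) name <- sprintf("p%d", seq_along(start))
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, stringsAsFactors = FALSE)
}

# mean signal of `track` over [start, end) by expanding runs to a dense
# per-base vector (intervals must be modest, <= ~10 kb)
dense_intensity <- function(track, chrom, start, end) {
  v <- numeric(end - start)
  runs <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    a <- max(runs$start[i], start)
    b <- min(runs$end[i], end)
    if (b > a) v[(a - start + 1):(b - start)] <- runs$value[i]
  }
  mean(v)
}

# all-pairs edge distances between half-open intervals; returns every
# (anchor, query) pair with distance <= max_dist
brute_nearby <- function(anchors, queries, max_dist) {
  rows <- list()
  k <- 0
  for (i in seq_len(nrow(anchors))) {
    for (j in seq_len(nrow(queries))) {
      if (anchors$chrom[i] != queries$chrom[j]) next
      gap <- max(0, queries$start[j] - anchors$end[i],
                 anchors$start[i] - queries$end[j])
      if (gap <= max_dist) {
        k <- k + 1
        rows[[k]] <- data.frame(anchor = anchors$name[i],
                                query = queries$name[j],
                                edge_distance = gap,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) {
    return(data.frame(anchor = character(), query = character(),
                      edge_distance = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# textbook interpolated quantile: h = 1 + (N - 1) q over sorted values
manual_quantile <- function(values, q) {
  x <- sort(values)
  h <- 1 + (length(x) - 1) * q
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# random run-list track on one chromosome of length `len`
random_track <- function(len, n_runs = 30, chrom = "chr1") {
  cuts <- sort(sample.int(len - 1, 2 * n_runs))
  start <- cuts[seq(1, length(cuts), 2)]
  end <- cuts[seq(2, length(cuts), 2)]
  make_track(chrom, start, end, round(runif(n_runs, 0, 5), 3))
}

small_gene_table <- function() {
  data.frame(
    accession = c("NM_001", "NM_002", "NM_003", "NR_001", "NM_004"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "-", "+", "-"),
    tx_start = c(10000, 10000, 30000, 50000, 5000),
    tx_end = c(15000, 18000, 34000, 56000, 9000),
    gene_symbol = c("A", "A2", "B", "C", "D"),
    stringsAsFactors = FALSE
  )
}
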