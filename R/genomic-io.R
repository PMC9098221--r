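#' @importFrom stats quantile rnorm rpois runif setNames aggregate pbinom wilcox.test dnorm
#' @importFrom utils read.table write.table
NULL

# ---- interval validation ------------------------------------------------

# All coordinates in this package are 0-based half-open (BED/bedGraph
# native); refGene txStart/txEnd already use this convention.
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom))) {
    stop(sprintf("%s table has empty chromosome names", what), call. = FALSE)
  }
  if (any(df$start < 0)) {
    stop(sprintf("%s table has negative start coordinates", what), call. = FALSE)
  }
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1]
    stop(sprintf("%s table row %d has end <= start (%s:%d-%d)",
                 what, bad, df$chrom[bad], df$start[bad], df$end[bad]),
         call. = FALSE)
  }
  invisible(df)
}

# 0-based half-open -> IRanges (1-based closed), per chromosome
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# ---- signal tracks ------------------------------------------------------

#' Construct a coverage signal track
#'
#' A signal track is a piecewise-constant, non-negative coverage density
#' over a genome, stored as sorted non-overlapping runs
#' `(chrom, start, end, value)` in 0-based half-open coordinates.  Bases
#' not covered by any run have value 0.  This mirrors the sparse
#' semantics of the bedGraph format that MACS2-style pipelines emit.
#'
#' @param runs data.frame with columns `chrom`, `start`, `end`, `value`.
#' @return A `signal_track`: the validated, sorted run table with class
#'   attribute; total mass (sum of value x length) is available via
#'   [track_mass()].
#' @export
signal_track <- function(runs) {
  stopifnot(is.data.frame(runs))
  if (!"value" %in% names(runs)) stop("runs need a 'value' column", call. = FALSE)
  runs <- runs[, c("chrom", "start", "end", "value")]
  runs$chrom <- as.character(runs$chrom)
  runs$start <- as.numeric(runs$start)
  runs$end <- as.numeric(runs$end)
  runs$value <- as.numeric(runs$value)
  validate_intervals(runs, "signal track")
  if (nrow(runs) && any(runs$value < 0)) {
    stop("signal track values must be non-negative", call. = FALSE)
  }
  if (nrow(runs)) {
    runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
    rownames(runs) <- NULL
    same <- runs$chrom[-1] == runs$chrom[-nrow(runs)]
    if (nrow(runs) > 1 && any(same & runs$start[-1] < runs$end[-nrow(runs)])) {
      bad <- which(same & runs$start[-1] < runs$end[-nrow(runs)])[1]
      stop(sprintf("overlapping runs on %s near position %d",
                   runs$chrom[bad], as.integer(runs$start[bad + 1])),
           call. = FALSE)
    }
  }
  class(runs) <- c("signal_track", "data.frame")
  runs
}

#' Total mass of a signal track
#'
#' @param track a [signal_track()].
#' @return Sum over runs of value x run length (in signal x bp units).
#' @export
track_mass <- function(track) {
  if (nrow(track) == 0) return(0)
  sum(track$value * (track$end - track$start))
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal track: %d runs on %d chromosome(s), total mass %.6g\n",
              nrow(x), length(unique(x$chrom)), track_mass(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Rescale a track to a target total mass
#'
#' Depth normalization: every run value is multiplied by
#' `target_mass / track_mass(track)`, the track-level analogue of
#' normalizing coverage with respect to total read counts.  Tracks
#' normalized to the same target mass are directly comparable.
#'
#' @param track a [signal_track()].
#' @param target_mass positive total mass of the output (default 1e6).
#' @return A `signal_track` of total mass `target_mass`.
#' @export
normalize_track <- function(track, target_mass = 1e6) {
  stopifnot(target_mass > 0)
  m <- track_mass(track)
  if (m <= 0) {
    stop("cannot normalize a track with zero total mass", call. = FALSE)
  }
  track$value <- track$value * (target_mass / m)
  track
}

# ---- readers ------------------------------------------------------------

read_genomic_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

parse_coord <- function(x, path, lineno, what) {
  suppressWarnings(v <- as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad)) {
    stop(sprintf("%s: line %d: malformed %s coordinate '%s'",
                 path, lineno[which(bad)[1]], what, x[which(bad)[1]]),
         call. = FALSE)
  }
  v
}

#' Read a BED file of peaks
#'
#' Parses BED3/BED5-style tab-separated files with native 0-based
#' half-open coordinates.  Column 4 becomes the peak name (auto-generated
#' `peak_<i>` when absent), column 5 the score.  `track`, `browser` and
#' `#` lines are skipped.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score` (NA when the file has no score column).
#' @export
read_bed <- function(path) {
  src <- read_genomic_lines(path)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(src$lines)) return(empty)
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("%s: line %d has fewer than 3 tab-separated columns",
                 path, src$lineno[which(nf < 3)[1]]), call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  df <- data.frame(
    chrom = get(1),
    start = parse_coord(get(2), path, src$lineno, "start"),
    end = parse_coord(get(3), path, src$lineno, "end"),
    name = get(4),
    score = suppressWarnings(as.numeric(get(5))),
    stringsAsFactors = FALSE
  )
  auto <- is.na(df$name) | !nzchar(df$name)
  df$name[auto] <- sprintf("peak_%d", which(auto))
  bad <- df$end <= df$start
  if (any(bad)) {
    stop(sprintf("%s: line %d: end <= start", path, src$lineno[which(bad)[1]]),
         call. = FALSE)
  }
  if (anyDuplicated(df$name)) df$name <- make.unique(df$name, sep = "_")
  validate_intervals(df, "BED")
  df
}

#' Write peaks to a BED file
#'
#' Emits BED5 when scores are present, BED4 otherwise; `read_bed()` on
#' the result reproduces the input exactly.
#'
#' @param peaks data.frame as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  validate_intervals(peaks, "BED")
  has_score <- "score" %in% names(peaks) && any(!is.na(peaks$score))
  lines <- if (nrow(peaks) == 0) character() else if (has_score) {
    sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom, as.integer(peaks$start),
            as.integer(peaks$end), peaks$name,
            ifelse(is.na(peaks$score), "0", sprintf("%.17g", peaks$score)))
  } else {
    sprintf("%s\t%d\t%d\t%s", peaks$chrom, as.integer(peaks$start),
            as.integer(peaks$end), peaks$name)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage file into a signal track
#'
#' Four-column bedGraph with 0-based half-open runs; values must be
#' non-negative and runs on one chromosome must not overlap (bookended
#' runs are legal and kept unmerged).
#'
#' @param path path to a bedGraph file.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path) {
  src <- read_genomic_lines(path)
  if (!length(src$lines)) {
    return(signal_track(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), value = numeric())))
  }
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop(sprintf("%s: line %d has fewer than 4 columns", path,
                 src$lineno[which(nf < 4)[1]]), call. = FALSE)
  }
  get <- function(i) vapply(fields, `[`, "", i)
  value <- suppressWarnings(as.numeric(get(4)))
  if (anyNA(value)) {
    stop(sprintf("%s: line %d: non-numeric value", path,
                 src$lineno[which(is.na(value))[1]]), call. = FALSE)
  }
  if (any(value < 0)) {
    stop(sprintf("%s: line %d: negative value", path,
                 src$lineno[which(value < 0)[1]]), call. = FALSE)
  }
  signal_track(data.frame(
    chrom = get(1),
    start = parse_coord(get(2), path, src$lineno, "start"),
    end = parse_coord(get(3), path, src$lineno, "end"),
    value = value,
    stringsAsFactors = FALSE
  ))
}

#' Write a signal track as bedGraph
#'
#' Zero-valued runs are omitted (they are implicit in the sparse
#' bedGraph convention), so write-then-read round-trips up to removal of
#' zero runs.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  keep <- track$value != 0
  lines <- sprintf("%s\t%d\t%d\t%.17g", track$chrom[keep],
                   as.integer(track$start[keep]), as.integer(track$end[keep]),
                   track$value[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Read a refGene-style gene table
#'
#' Tab-delimited UCSC refGene dialect: accession, chrom, strand, txStart,
#' txEnd (0-based half-open), optional gene symbol.  With
#' `has_bin_column` the leading numeric bin column is discarded.
#' Duplicate rows are retained; TSS deduplication is a separate explicit
#' step ([deduplicate_tss()]).
#'
#' @param path path to the table.
#' @param has_bin_column logical; `TRUE` when column 1 is the UCSC bin.
#' @return data.frame with columns `accession`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `gene_symbol` (NA when absent).
#' @export
read_gene_table <- function(path, has_bin_column = FALSE) {
  src <- read_genomic_lines(path)
  empty <- data.frame(accession = character(), chrom = character(),
                      strand = character(), tx_start = numeric(),
                      tx_end = numeric(), gene_symbol = character(),
                      stringsAsFactors = FALSE)
  if (!length(src$lines)) return(empty)
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  if (has_bin_column) fields <- lapply(fields, `[`, -1L)
  nf <- lengths(fields)
  if (any(nf < 5)) {
    stop(sprintf("%s: line %d has fewer than %d columns", path,
                 src$lineno[which(nf < 5)[1]], 5 + has_bin_column), call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  strand <- get(3)
  if (!all(strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1]
    stop(sprintf("%s: line %d: strand must be '+' or '-', got '%s'",
                 path, src$lineno[bad], strand[bad]), call. = FALSE)
  }
  df <- data.frame(
    accession = get(1),
    chrom = get(2),
    strand = strand,
    tx_start = parse_coord(get(4), path, src$lineno, "txStart"),
    tx_end = parse_coord(get(5), path, src$lineno, "txEnd"),
    gene_symbol = get(6),
    stringsAsFactors = FALSE
  )
  if (any(df$tx_end <= df$tx_start)) {
    bad <- which(df$tx_end <= df$tx_start)[1]
    stop(sprintf("%s: line %d: txEnd <= txStart", path, src$lineno[bad]),
         call. = FALSE)
  }
  df
}

#' Write a gene table in refGene dialect
#'
#' @param genes data.frame as returned by [read_gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  sym <- if ("gene_symbol" %in% names(genes)) genes$gene_symbol else NA
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s", genes$accession, genes$chrom,
                   genes$strand, as.integer(genes$tx_start),
                   as.integer(genes$tx_end),
                   ifelse(is.na(sym), "", sym))
  writeLines(sub("\t$", "", lines), path)
  invisible(path)
}
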