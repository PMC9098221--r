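# Promoter-TSS catalog construction: protein-coding filter, TSS
# deduplication, and transcription-oriented quantification windows.

#' Parameters for promoter catalog construction
#'
#' @param min_gene_length minimum transcript length in bp, exclusive:
#'   only genes strictly longer are kept (default 2000).
#' @param coding_prefix accession prefix marking protein-coding
#'   transcripts (default `"NM_"`; RefSeq `NR_` records are non-coding).
#' @param upstream_bp window extent upstream of the TSS (default 500).
#' @param downstream_bp window extent downstream of the TSS (default 1000).
#' @return A validated parameter list of class `catalog_params`.
#' @export
catalog_params <- function(min_gene_length = 2000, coding_prefix = "NM_",
                           upstream_bp = 500, downstream_bp = 1000) {
  stopifnot(min_gene_length >= 0, upstream_bp > 0, downstream_bp > 0,
            is.character(coding_prefix), nzchar(coding_prefix))
  structure(list(min_gene_length = min_gene_length,
                 coding_prefix = coding_prefix,
                 upstream_bp = upstream_bp,
                 downstream_bp = downstream_bp),
            class = "catalog_params")
}

#' Select protein-coding genes above a length threshold
#'
#' Keeps gene records whose accession starts with the coding prefix and
#' whose transcript span is strictly longer than `min_gene_length`.
#'
#' @param genes gene table from [read_gene_table()].
#' @param params a [catalog_params()].
#' @return The filtered gene table.
#' @export
select_protein_coding <- function(genes, params = catalog_params()) {
  keep <- startsWith(genes$accession, params$coding_prefix) &
    (genes$tx_end - genes$tx_start) > params$min_gene_length
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TSS of a record in 0-based coordinates: first transcribed base.
# On the - strand the 5' end of a half-open span [start, end) is end - 1.
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
}

#' Deduplicate transcripts into a promoter-TSS catalog
#'
#' Transcripts sharing the exact same TSS position (and chromosome and
#' strand: divergent promoters at one coordinate are distinct regulatory
#' units) are merged into one promoter-TSS entry listing all member
#' accessions.
#'
#' @param genes stranded gene table (typically after
#'   [select_protein_coding()]).
#' @param params a [catalog_params()]; sets the window geometry stored
#'   alongside each promoter.
#' @return data.frame sorted by `(chrom, tss)` with columns `name`
#'   (`chrom:tss:strand`), `chrom`, `strand`, `tss`, `window_start`,
#'   `window_end`, `members` (comma-joined accessions), `n_members`.
#' @export
deduplicate_tss <- function(genes, params = catalog_params()) {
  empty <- data.frame(name = character(), chrom = character(),
                      strand = character(), tss = numeric(),
                      window_start = numeric(), window_end = numeric(),
                      members = character(), n_members = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(genes) == 0) return(empty)
  stopifnot(all(genes$strand %in% c("+", "-")))
  tss <- gene_tss(genes)
  key <- paste(genes$chrom, genes$strand, tss, sep = "\r")
  ord <- order(genes$accession)
  members <- vapply(split(genes$accession[ord], key[ord]),
                    paste, "", collapse = ",")
  first <- !duplicated(key)
  cat_df <- data.frame(
    chrom = genes$chrom[first],
    strand = genes$strand[first],
    tss = tss[first],
    stringsAsFactors = FALSE
  )
  k <- key[first]
  cat_df$members <- unname(members[k])
  cat_df$n_members <- lengths(strsplit(cat_df$members, ",", fixed = TRUE))
  cat_df <- cat_df[order(cat_df$chrom, cat_df$tss), , drop = FALSE]
  win <- promoter_window(cat_df, params)
  cat_df$window_start <- win$start
  cat_df$window_end <- win$end
  cat_df$name <- sprintf("%s:%d:%s", cat_df$chrom, as.integer(cat_df$tss),
                         cat_df$strand)
  rownames(cat_df) <- NULL
  cat_df[, c("name", "chrom", "strand", "tss", "window_start", "window_end",
             "members", "n_members")]
}

# Transcription-oriented interval at offsets (a, b) around a TSS, in
# 0-based half-open coordinates.  + strand: [tss + a, tss + b).  - strand
# mirror image (so "upstream" stays transcription-upstream):
# [tss - b + 1, tss - a + 1).
oriented_interval <- function(chrom, tss, strand, a, b,
                              chrom_sizes = NULL) {
  plus <- strand == "+"
  start <- ifelse(plus, tss + a, tss - b + 1)
  end <- ifelse(plus, tss + b, tss - a + 1)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[chrom])
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Quantification window around a promoter-TSS
#'
#' The -upstream/+downstream window (default -500/+1000 bp) around the
#' TSS, oriented along transcription and therefore mirrored on the
#' minus strand; clamped at 0 and, when `chrom_sizes` is given, at the
#' chromosome end.
#'
#' @param promoters data.frame with `chrom`, `tss`, `strand` columns
#'   (e.g. a catalog from [deduplicate_tss()]).
#' @param params a [catalog_params()].
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return data.frame of intervals `chrom`, `start`, `end`.
#' @export
promoter_window <- function(promoters, params = catalog_params(),
                            chrom_sizes = NULL) {
  oriented_interval(promoters$chrom, promoters$tss, promoters$strand,
                    -params$upstream_bp, params$downstream_bp, chrom_sizes)
}

#' Build a promoter-TSS catalog from a gene table
#'
#' Convenience wrapper: [select_protein_coding()] then
#' [deduplicate_tss()].
#'
#' @inheritParams select_protein_coding
#' @return Promoter catalog data.frame; see [deduplicate_tss()].
#' @export
build_promoter_catalog <- function(genes, params = catalog_params()) {
  deduplicate_tss(select_protein_coding(genes, params), params)
}
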