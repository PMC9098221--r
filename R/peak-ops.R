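# Peak-set algebra: merging, nearby assignment with duplication
# semantics, equal High/Low splits, and a binomial annotation
# enrichment.

#' Merge peak sets into a disjoint union
#'
#' Interval union per chromosome; overlapping *and* bookended (end ==
#' start) intervals coalesce, since half-open adjacency represents
#' contiguous coverage.  Output is sorted by `(chrom, start)`, disjoint,
#' and named `merged_<i>`.  Idempotent and order-invariant in its
#' arguments.
#'
#' @param ... one or more peak data.frames (or a single list of them).
#' @return Peak data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
merge_peaks <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (!length(sets)) stop("need at least one peak set", call. = FALSE)
  all_pk <- do.call(rbind, lapply(sets, function(p) {
    validate_intervals(p, "peak")
    p[, c("chrom", "start", "end")]
  }))
  if (nrow(all_pk) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), stringsAsFactors = FALSE))
  }
  parts <- lapply(split(all_pk, all_pk$chrom), function(p) {
    r <- IRanges::reduce(as_iranges0(p$start, p$end))
    data.frame(chrom = p$chrom[1], start = IRanges::start(r) - 1,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  out$name <- sprintf("merged_%d", seq_len(nrow(out)))
  out
}

#' Assign nearby query peaks to anchor peaks
#'
#' Emits one row for every `(anchor, query)` pair whose edge distance is
#' at most `max_dist` (0 for overlapping or bookended intervals).
#' Anchors with several in-range queries appear on several rows --
#' deliberately *without* deduplication -- and anchors with no in-range
#' query are absent from the output.  With `unique_query = TRUE` each
#' query is additionally kept only with its single closest anchor
#' ("closest" semantics; ties broken toward the smaller anchor start,
#' then name).
#'
#' @param anchors,queries peak data.frames with `chrom`, `start`, `end`,
#'   `name`.
#' @param max_dist maximum edge distance in bp (inclusive).
#' @param unique_query keep only the closest anchor per query.
#' @return data.frame with `anchor`, `query`, `edge_distance` plus
#'   `anchor_idx`, `query_idx` row indices.
#' @export
assign_nearby <- function(anchors, queries, max_dist = 2000,
                          unique_query = FALSE) {
  validate_intervals(anchors, "anchor")
  validate_intervals(queries, "query")
  stopifnot(max_dist >= 0)
  empty <- data.frame(anchor = character(), query = character(),
                      edge_distance = numeric(), anchor_idx = integer(),
                      query_idx = integer(), stringsAsFactors = FALSE)
  if (nrow(anchors) == 0 || nrow(queries) == 0) return(empty)
  rows <- list()
  for (ch in intersect(unique(anchors$chrom), unique(queries$chrom))) {
    ai <- which(anchors$chrom == ch)
    qi <- which(queries$chrom == ch)
    ar <- as_iranges0(anchors$start[ai], anchors$end[ai])
    qr <- as_iranges0(queries$start[qi], queries$end[qi])
    hits <- IRanges::findOverlaps(ar, qr, maxgap = max_dist)
    if (!length(hits)) next
    h_a <- ai[S4Vectors::queryHits(hits)]
    h_q <- qi[S4Vectors::subjectHits(hits)]
    d <- IRanges::distance(ar[S4Vectors::queryHits(hits)],
                           qr[S4Vectors::subjectHits(hits)])
    rows[[ch]] <- data.frame(anchor = anchors$name[h_a],
                             query = queries$name[h_q],
                             edge_distance = as.numeric(d),
                             anchor_idx = h_a, query_idx = h_q,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$anchor_idx, out$query_idx), , drop = FALSE]
  if (unique_query) {
    ord <- order(out$query_idx, out$edge_distance,
                 anchors$start[out$anchor_idx], out$anchor)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$query_idx), , drop = FALSE]
    out <- out[order(out$anchor_idx, out$query_idx), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Split peaks into equal High and Low groups by intensity
#'
#' Sorts descending by the key intensity (ties broken by `(chrom,
#' start)` for bit-reproducibility); High is the first `floor(N/2)`
#' peaks, Low the remaining `ceiling(N/2)` -- so for odd N the Low group
#' is the larger by one, e.g. 34,771 peaks split 17,385 High / 17,386
#' Low.
#'
#' @param peaks peak data.frame.
#' @param key_intensity numeric ranking key, one value per peak.
#' @return List of class `high_low_split` with elements `high`, `low`
#'   (ordered peak data.frames, each carrying its `key` column).
#' @export
split_high_low <- function(peaks, key_intensity) {
  if (nrow(peaks) == 0) stop("cannot split an empty peak set", call. = FALSE)
  if (length(key_intensity) != nrow(peaks)) {
    stop("need one key per peak", call. = FALSE)
  }
  ord <- order(-key_intensity, peaks$chrom, peaks$start)
  peaks <- peaks[ord, , drop = FALSE]
  peaks$key <- key_intensity[ord]
  rownames(peaks) <- NULL
  n_high <- nrow(peaks) %/% 2
  structure(list(high = peaks[seq_len(n_high), , drop = FALSE],
                 low = peaks[setdiff(seq_len(nrow(peaks)), seq_len(n_high)), ,
                             drop = FALSE]),
            class = "high_low_split")
}

#' @export
print.high_low_split <- function(x, ...) {
  cat(sprintf("high/low split: %d high, %d low\n", nrow(x$high), nrow(x$low)))
  invisible(x)
}

#' Annotation enrichment of peaks by binomial test
#'
#' For each named annotation interval set: a peak is a member when its
#' midpoint lies in the (reduced) annotation; expected membership under
#' a uniform genome background is `N x annotation_bp / genome_size_bp`.
#' Reports `log2((observed + 0.5) / (expected + 0.5))` and a binomial
#' tail p-value (`P(X >= observed)` when observed >= expected, lower
#' tail otherwise).  A simplified, documented analogue of
#' annotation-enrichment tools; not comparable in magnitude to
#' HOMER-style hierarchical annotation statistics.
#'
#' @param peaks peak data.frame.
#' @param annotations named list of interval data.frames.
#' @param genome_size_bp total genome size used as background.
#' @return data.frame with `annotation`, `observed`, `expected`,
#'   `log2_enrichment`, `p_value`.
#' @export
annotation_enrichment <- function(peaks, annotations, genome_size_bp) {
  validate_intervals(peaks, "peak")
  stopifnot(is.list(annotations), length(names(annotations)) == length(annotations),
            genome_size_bp > 0)
  mid <- floor((peaks$start + peaks$end) / 2)
  n <- nrow(peaks)
  rows <- lapply(names(annotations), function(nm) {
    ann <- annotations[[nm]]
    validate_intervals(ann, sprintf("annotation '%s'", nm))
    red <- merge_peaks(ann)
    bp <- sum(red$end - red$start)
    if (bp == 0) {
      warning(sprintf("annotation '%s' has zero length; skipped", nm))
      return(NULL)
    }
    if (bp > genome_size_bp) {
      stop("annotation span exceeds genome size", call. = FALSE)
    }
    inside <- logical(n)
    for (ch in unique(red$chrom)) {
      pi <- which(peaks$chrom == ch)
      if (!length(pi)) next
      a <- red[red$chrom == ch, , drop = FALSE]
      # midpoint mid is inside [start, end) iff start <= mid < end
      idx <- findInterval(mid[pi], a$start)
      inside[pi] <- idx > 0 & mid[pi] < a$end[pmax(idx, 1)]
    }
    obs <- sum(inside)
    p <- bp / genome_size_bp
    expd <- n * p
    pval <- if (obs >= expd) {
      stats::pbinom(obs - 1, n, p, lower.tail = FALSE)
    } else {
      stats::pbinom(obs, n, p)
    }
    data.frame(annotation = nm, observed = obs, expected = expd,
               log2_enrichment = log2((obs + 0.5) / (expd + 0.5)),
               p_value = pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(annotation = character(), observed = integer(),
                      expected = numeric(), log2_enrichment = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
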