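# End-to-end orchestration: catalog -> classify -> cluster -> peak
# assignment -> differential accessibility -> DEG linkage -> summary.

#' Pipeline configuration
#'
#' Inputs may be file paths (read with the package readers) or
#' in-memory objects (gene tables, [signal_track()]s or lists of
#' replicate tracks, peak data.frames, expression data.frames).  Every
#' threshold defaults to its standard printed constant: -500/+1000 bp
#' windows, Q1/Q3 quartile cuts, 1.5-fold change, 2 kb / 500 bp link
#' distances, p <= 0.05 & fold change >= 1.5 DEGs.
#'
#' @param genes gene table (path or data.frame).
#' @param h3k4me3,h3k27me3 mark tracks (path/track or list of
#'   replicates).
#' @param brg1_control,brg1_kd,atac_control,atac_kd coverage tracks.
#' @param brg1_peaks,atac_peaks peak sets (path or data.frame).
#' @param expression expression table (path or data.frame); optional
#'   (`NULL` skips the DEG stage).
#' @param catalog a [catalog_params()].
#' @param classifier a [classifier_params()].
#' @param offsets a [region_offsets()].
#' @param differential a [diff_params()].
#' @param deg_p_max,deg_fc_min DEG thresholds.
#' @param brg1_link_dist,atac_link_dist DEG-TSS link distances (bp).
#' @param assign_max_dist peak-to-peak assignment distance (bp).
#' @param target_mass common track normalization mass.
#' @param chrom_sizes optional named chromosome lengths.
#' @param out_dir optional directory for per-stage TSV outputs.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genes, h3k4me3, h3k27me3, brg1_control, brg1_kd,
                            atac_control, atac_kd, brg1_peaks, atac_peaks,
                            expression = NULL,
                            catalog = catalog_params(),
                            classifier = classifier_params(),
                            offsets = region_offsets(),
                            differential = diff_params(),
                            deg_p_max = 0.05, deg_fc_min = 1.5,
                            brg1_link_dist = 2000, atac_link_dist = 500,
                            assign_max_dist = 2000,
                            target_mass = 1e6, chrom_sizes = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(catalog, "catalog_params"),
            inherits(classifier, "classifier_params"),
            inherits(offsets, "region_offsets"),
            inherits(differential, "diff_params"),
            brg1_link_dist >= 0, atac_link_dist >= 0, assign_max_dist >= 0,
            target_mass > 0)
  structure(list(genes = genes, h3k4me3 = h3k4me3, h3k27me3 = h3k27me3,
                 brg1_control = brg1_control, brg1_kd = brg1_kd,
                 atac_control = atac_control, atac_kd = atac_kd,
                 brg1_peaks = brg1_peaks, atac_peaks = atac_peaks,
                 expression = expression, catalog = catalog,
                 classifier = classifier, offsets = offsets,
                 differential = differential, deg_p_max = deg_p_max,
                 deg_fc_min = deg_fc_min, brg1_link_dist = brg1_link_dist,
                 atac_link_dist = atac_link_dist,
                 assign_max_dist = assign_max_dist,
                 target_mass = target_mass, chrom_sizes = chrom_sizes,
                 out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

load_track <- function(x) {
  if (is.character(x)) return(read_bedgraph(x))
  if (inherits(x, "signal_track")) return(x)
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, load_track))
  stop("expected a bedGraph path or signal_track", call. = FALSE)
}

load_peaks <- function(x) if (is.character(x)) read_bed(x) else x

load_genes <- function(x, ...) {
  if (is.character(x)) read_gene_table(x, ...) else x
}

#' Run the full promoter chromatin analysis
#'
#' Executes the stages in dependency order -- promoter catalog, promoter
#' classification, TSS clustering, peak assignment and High/Low split,
#' differential accessibility, DEG linkage -- writes per-stage TSVs when
#' `out_dir` is set, and returns all tables plus a deterministic
#' summary.  A failing stage aborts with an error naming that stage.
#'
#' @param config a [pipeline_config()].
#' @return List of class `bivalscape_pipeline` with elements `catalog`,
#'   `classes`, `clusters` (full per-TSS table), `decreased` (selected
#'   decreased TSSs), `assignments`, `split_sizes`, `differential_atac`
#'   (per class x cluster), `deg_calls`, `deg_links`, `deg_differential`
#'   and `summary` (named key/value table).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config

  catalog <- run_stage("catalog", {
    build_promoter_catalog(load_genes(p$genes), p$catalog)
  })

  classes <- run_stage("classify", {
    windows <- catalog[, c("chrom", "window_start", "window_end")]
    names(windows) <- c("chrom", "start", "end")
    k4 <- mark_intensity(load_track(p$h3k4me3), windows, p$target_mass)
    k27 <- mark_intensity(load_track(p$h3k27me3), windows, p$target_mass)
    data.frame(name = catalog$name, h3k4me3 = k4, h3k27me3 = k27,
               class = classify_promoters(k4, k27, p$classifier),
               stringsAsFactors = FALSE)
  })

  clusters <- run_stage("cluster", {
    ctrl <- normalize_track(load_track(p$brg1_control), p$target_mass)
    kd <- normalize_track(load_track(p$brg1_kd), p$target_mass)
    tab <- cluster_tss(catalog, ctrl, kd, p$offsets, p$differential,
                       p$chrom_sizes)
    tab$class <- classes$class
    tab
  })
  decreased <- clusters[(clusters$up_call == "DECREASED" |
                           clusters$down_call == "DECREASED") &
                          clusters$class != "H3K4me3_LOW", , drop = FALSE]
  rownames(decreased) <- NULL

  assign_out <- run_stage("peak-assignment", {
    brg1_pk <- load_peaks(p$brg1_peaks)
    atac_pk <- load_peaks(p$atac_peaks)
    merged <- merge_peaks(brg1_pk)
    assignments <- assign_nearby(brg1_pk, atac_pk, p$assign_max_dist)
    ctrl <- normalize_track(load_track(p$brg1_control), p$target_mass)
    # Fig 4G-style row set: assignment rows without deduplication,
    # ranked by control occupancy at the anchor peak
    anchor_rows <- brg1_pk[assignments$anchor_idx, , drop = FALSE]
    split <- if (nrow(anchor_rows)) {
      split_high_low(anchor_rows, window_intensity(ctrl, anchor_rows))
    } else NULL
    list(brg1_pk = brg1_pk, atac_pk = atac_pk, merged = merged,
         assignments = assignments, split = split)
  })

  differential_atac <- run_stage("differential-accessibility", {
    actrl <- normalize_track(load_track(p$atac_control), p$target_mass)
    akd <- normalize_track(load_track(p$atac_kd), p$target_mass)
    if (nrow(decreased) == 0) {
      data.frame(class = character(), cluster = character(), n = integer(),
                 mean_log2fc = numeric(), p_value = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      centers <- define_regions(decreased, p$offsets, p$chrom_sizes)$center
      cc <- window_intensity(actrl, centers)
      ck <- window_intensity(akd, centers)
      lfc <- log2_ratio(ck, cc, p$differential)
      grp <- data.frame(class = as.character(decreased$class),
                        cluster = as.character(decreased$cluster),
                        ctrl = cc, kd = ck, lfc = lfc,
                        stringsAsFactors = FALSE)
      parts <- split(grp, list(grp$class, grp$cluster), drop = TRUE)
      out <- do.call(rbind, lapply(parts, function(g) {
        pv <- tryCatch(rank_tests(g$kd, g$ctrl, paired = TRUE),
                       error = function(e) NA_real_)
        data.frame(class = g$class[1], cluster = g$cluster[1], n = nrow(g),
                   mean_log2fc = mean(g$lfc), p_value = pv,
                   stringsAsFactors = FALSE)
      }))
      out <- out[order(out$class, out$cluster), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
  })

  deg <- if (is.null(p$expression)) NULL else run_stage("deg-linkage", {
    records <- if (is.character(p$expression)) {
      read_expression_table(p$expression)
    } else p$expression
    calls <- filter_degs(records, p$deg_p_max, p$deg_fc_min)
    down_genes <- records$gene[calls == "DOWN"]
    # map DEGs to catalog TSSs through member accessions
    members <- strsplit(catalog$members, ",", fixed = TRUE)
    row_of <- rep(seq_len(nrow(catalog)), lengths(members))
    acc <- unlist(members)
    hit <- unique(row_of[acc %in% down_genes])
    deg_tss <- catalog[sort(hit), , drop = FALSE]
    links <- link_peaks_to_deg_tss(deg_tss, assign_out$brg1_pk,
                                   assign_out$atac_pk,
                                   p$brg1_link_dist, p$atac_link_dist)
    bctrl <- normalize_track(load_track(p$brg1_control), p$target_mass)
    bkd <- normalize_track(load_track(p$brg1_kd), p$target_mass)
    actrl <- normalize_track(load_track(p$atac_control), p$target_mass)
    akd <- normalize_track(load_track(p$atac_kd), p$target_mass)
    linked_b <- assign_out$brg1_pk[assign_out$brg1_pk$name %in%
                                     links$brg1_peak, , drop = FALSE]
    linked_a <- assign_out$atac_pk[assign_out$atac_pk$name %in%
                                     links$atac_peak, , drop = FALSE]
    diff_b <- if (nrow(linked_b)) {
      mean_differential(linked_b, bctrl, bkd, p$differential)$mean_log2fc
    } else NA_real_
    diff_a <- if (nrow(linked_a)) {
      mean_differential(linked_a, actrl, akd, p$differential)$mean_log2fc
    } else NA_real_
    list(calls = calls, records = records, links = links,
         mean_brg1_log2fc = diff_b, mean_atac_log2fc = diff_a)
  })

  class_counts <- table(classes$class)
  cluster_counts <- table(decreased$cluster)
  kv <- c(
    n_promoters = nrow(catalog),
    setNames(as.integer(class_counts), paste0("n_", names(class_counts))),
    n_decreased_tss = nrow(decreased),
    setNames(as.integer(cluster_counts),
             paste0("n_", tolower(names(cluster_counts)))),
    n_merged_peaks = nrow(assign_out$merged),
    n_assignments = nrow(assign_out$assignments),
    n_high = if (is.null(assign_out$split)) 0L else nrow(assign_out$split$high),
    n_low = if (is.null(assign_out$split)) 0L else nrow(assign_out$split$low)
  )
  if (!is.null(deg)) {
    kv <- c(kv,
            n_deg_up = sum(deg$calls == "UP"),
            n_deg_down = sum(deg$calls == "DOWN"),
            mean_brg1_log2fc_deg = round(deg$mean_brg1_log2fc, 6),
            mean_atac_log2fc_deg = round(deg$mean_atac_log2fc, 6))
  }
  summary_tab <- data.frame(key = names(kv), value = unname(kv),
                            stringsAsFactors = FALSE)

  result <- structure(list(
    catalog = catalog, classes = classes, clusters = clusters,
    decreased = decreased, merged_peaks = assign_out$merged,
    assignments = assign_out$assignments,
    split_sizes = c(high = kv[["n_high"]], low = kv[["n_low"]]),
    differential_atac = differential_atac,
    deg = deg, summary = summary_tab, config = p
  ), class = "bivalscape_pipeline")

  if (!is.null(p$out_dir)) {
    dir.create(p$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) utils::write.table(
      df, file.path(p$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(catalog, "catalog.tsv")
    wt(classes, "classes.tsv")
    wt(clusters, "clusters.tsv")
    wt(decreased, "decreased_tss.tsv")
    wt(assign_out$merged, "merged_peaks.tsv")
    wt(assign_out$assignments, "assignments.tsv")
    wt(differential_atac, "differential_atac.tsv")
    if (!is.null(deg)) wt(deg$links, "deg_links.tsv")
    wt(summary_tab, "summary.tsv")
  }
  result
}

#' @export
print.bivalscape_pipeline <- function(x, ...) {
  cat("promoter chromatin pipeline\n")
  cat(sprintf("  promoters: %d  (%s)\n", nrow(x$catalog),
              paste(sprintf("%s=%d", sub("^n_", "", x$summary$key[2:4]),
                            as.integer(x$summary$value[2:4])),
                    collapse = ", ")))
  cat(sprintf("  decreased TSSs: %d; merged peaks: %d; assignments: %d (high %s / low %s)\n",
              nrow(x$decreased), nrow(x$merged_peaks), nrow(x$assignments),
              x$split_sizes[["high"]], x$split_sizes[["low"]]))
  if (!is.null(x$deg)) {
    cat(sprintf("  DEGs: %d up, %d down; mean log2FC at down-DEG peaks: BRG1 %.3f, ATAC %.3f\n",
                sum(x$deg$calls == "UP"), sum(x$deg$calls == "DOWN"),
                x$deg$mean_brg1_log2fc, x$deg$mean_atac_log2fc))
  }
  invisible(x)
}
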