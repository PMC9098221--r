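# Synthetic chromatin simulator: refGene-style gene tables, promoter
# class-structured coverage tracks with -1/+1 nucleosome occupancy
# bumps flanking an accessible NFR, knockdown effects by cluster,
# matched peak sets, an expression table, and a ground-truth table.

#' Configuration of the synthetic chromatin generator
#'
#' Defaults describe a small but fully structured genome: genes on a
#' regular slot grid (so promoter neighbourhoods never collide), a
#' quarter of promoters in each extreme chromatin state mirroring the
#' observed H3K4me3-Low / H3K4me3-Only / bivalent ratios, remodeler
#' occupancy as two Gaussian bumps at the -1/+1 nucleosome positions
#' flanking a nucleosome-free region, accessibility as a single bump at
#' the TSS, per-class mark plateaus over the -500/+1000 promoter
#' window, and Poisson fragment-count noise binned to runs.
#'
#' @param seed integer fixing all randomness.
#' @param n_chroms,chrom_length_bp genome shape (default 4 x 3 Mb).
#' @param n_genes exact number of gene records emitted (default 600).
#' @param fraction_noncoding fraction of `NR_` records (default 0.1).
#' @param fraction_short fraction of sub-2 kb coding genes (default 0.1).
#' @param fraction_duplicate_tss fraction of records that duplicate the
#'   exact TSS of another coding gene (default 0.1).
#' @param class_proportions promoter-class simplex over
#'   `H3K4me3_LOW`/`H3K4me3_ONLY`/`BIVALENT` (default .25/.51/.24).
#' @param mark_levels per-class mean H3K4me3/H3K27me3 densities.
#' @param brg1_architecture list: `upstream_offset`/`downstream_offset`
#'   bp of the -1/+1 bump centres relative to the TSS (defaults
#'   -200/+150), Gaussian `sigma` (50 bp), per-class `amplitude`
#'   (high for Only, moderate for bivalent, low for Low).
#' @param atac list: NFR bump `sigma` (60 bp) and per-class `amplitude`.
#' @param cluster_proportions simplex over `Cluster1..5` plus
#'   `UNAFFECTED`.
#' @param kd_effect_log2 6 x 2 matrix of injected (upstream, downstream)
#'   log2 fold-changes per cluster.
#' @param noise list: `enabled`, `depth` (fragment-sampling depth
#'   multiplier), `bin_bp` (run width for count binning, default 25).
#' @param background_density uniform signal floor added within promoter
#'   neighbourhoods (default 0).
#' @param decoy_peaks number of desert decoy peaks per chromosome added
#'   to the remodeler peak set (default 0).
#' @param expression list: `p_down` chance that a promoter with an
#'   injected occupancy loss is a down-regulated DEG, `p_up` chance of
#'   an up DEG elsewhere.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    n_chroms = 4, chrom_length_bp = 3e6, n_genes = 600,
    fraction_noncoding = 0.1, fraction_short = 0.1,
    fraction_duplicate_tss = 0.1,
    class_proportions = c(H3K4me3_LOW = 0.25, H3K4me3_ONLY = 0.51,
                          BIVALENT = 0.24),
    mark_levels = list(
      h3k4me3 = c(H3K4me3_LOW = 0.5, H3K4me3_ONLY = 8, BIVALENT = 8),
      h3k27me3 = c(H3K4me3_LOW = 1, H3K4me3_ONLY = 0.5, BIVALENT = 6)),
    brg1_architecture = list(
      upstream_offset = -200, downstream_offset = 150, sigma = 50,
      amplitude = c(H3K4me3_LOW = 0.5, H3K4me3_ONLY = 10, BIVALENT = 5)),
    atac = list(sigma = 60,
                amplitude = c(H3K4me3_LOW = 0.5, H3K4me3_ONLY = 8,
                              BIVALENT = 4)),
    cluster_proportions = c(Cluster1 = 0.10, Cluster2 = 0.20,
                            Cluster3 = 0.20, Cluster4 = 0.05,
                            Cluster5 = 0.05, UNAFFECTED = 0.40),
    kd_effect_log2 = rbind(Cluster1 = c(-1.5, -1.5),
                           Cluster2 = c(-1.5, 0),
                           Cluster3 = c(0, -1.5),
                           Cluster4 = c(-1.5, 1.5),
                           Cluster5 = c(1.5, -1.5),
                           UNAFFECTED = c(0, 0)),
    noise = list(enabled = TRUE, depth = 1, bin_bp = 25),
    background_density = 0,
    decoy_peaks = 0,
    expression = list(p_down = 0.5, p_up = 0.05)) {
  stopifnot(seed == floor(seed), n_chroms >= 1, chrom_length_bp >= 1e5,
            n_genes >= 1)
  fr <- c(fraction_noncoding, fraction_short, fraction_duplicate_tss)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("noncoding/short/duplicate fractions must be >= 0 and sum to <= 1",
         call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-8 ||
      abs(sum(cluster_proportions) - 1) > 1e-8) {
    stop("class and cluster proportions must each sum to 1", call. = FALSE)
  }
  stopifnot(all(class_proportions >= 0), all(cluster_proportions >= 0),
            all(unlist(mark_levels) >= 0),
            all(brg1_architecture$amplitude >= 0), all(atac$amplitude >= 0),
            noise$depth > 0, noise$bin_bp >= 1, background_density >= 0)
  stopifnot(nrow(kd_effect_log2) == 6, ncol(kd_effect_log2) == 2)
  colnames(kd_effect_log2) <- c("up", "down")
  structure(list(
    seed = as.integer(seed), n_chroms = n_chroms,
    chrom_length_bp = chrom_length_bp, n_genes = n_genes,
    fraction_noncoding = fraction_noncoding, fraction_short = fraction_short,
    fraction_duplicate_tss = fraction_duplicate_tss,
    class_proportions = class_proportions, mark_levels = mark_levels,
    brg1_architecture = brg1_architecture, atac = atac,
    cluster_proportions = cluster_proportions,
    kd_effect_log2 = kd_effect_log2, noise = noise,
    background_density = background_density, decoy_peaks = decoy_peaks,
    expression = expression,
    gene_spacing_bp = 12000, margin_bp = 20000,
    support_flank_bp = 2000
  ), class = "synthetic_config")
}

sim_chrom_sizes <- function(config) {
  setNames(rep(config$chrom_length_bp, config$n_chroms),
           sprintf("chr%d", seq_len(config$n_chroms)))
}

# TSS slots on a regular grid, far from chromosome ends and from each
# other, so every promoter neighbourhood (+/- support_flank_bp) is
# private to one promoter.
sim_slots <- function(config) {
  sizes <- sim_chrom_sizes(config)
  slots <- do.call(rbind, lapply(names(sizes), function(ch) {
    pos <- seq(config$margin_bp, sizes[[ch]] - config$margin_bp,
               by = config$gene_spacing_bp)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  rownames(slots) <- NULL
  slots
}

#' Generate a refGene-style gene table with ground truth
#'
#' Emits exactly `n_genes` records: protein-coding genes longer than
#' 2 kb (the catalog-eligible class), plus the configured exact counts
#' of `NR_` non-coding records, sub-2 kb coding records, and coding
#' records duplicating the exact TSS of another eligible gene.  Every
#' eligible promoter receives a true chromatin class, a true knockdown
#' cluster, and injected (upstream, downstream) log2 effects drawn from
#' the configured simplices.  Deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @return List with `genes` (gene table, see [read_gene_table()]) and
#'   `truth` (one row per eligible promoter: `name`, `chrom`, `strand`,
#'   `tss`, `gene`, `class`, `cluster`, `up_effect`, `down_effect`).
#' @export
generate_gene_table <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  n_nr <- round(config$fraction_noncoding * n)
  n_short <- round(config$fraction_short * n)
  n_dup <- round(config$fraction_duplicate_tss * n)
  n_good <- n - n_nr - n_short - n_dup
  if (n_good < 1) stop("config leaves no eligible genes", call. = FALSE)
  slots <- sim_slots(config)
  n_slots_needed <- n_good + n_nr + n_short
  if (n_slots_needed > nrow(slots)) {
    stop("genome too small for the requested gene count", call. = FALSE)
  }
  picked <- slots[sort(sample.int(nrow(slots), n_slots_needed)), ,
                  drop = FALSE]
  kind <- sample(rep(c("good", "nr", "short"), c(n_good, n_nr, n_short)))
  strand <- sample(c("+", "-"), n_slots_needed, replace = TRUE)
  len <- ifelse(kind == "short",
                round(runif(n_slots_needed, 500, 1999)),
                round(runif(n_slots_needed, 2500, 8000)))
  tss <- picked$pos
  tx_start <- ifelse(strand == "+", tss, tss + 1 - len)
  tx_end <- ifelse(strand == "+", tss + len, tss + 1)
  acc_num <- seq_len(n_slots_needed)
  accession <- ifelse(kind == "nr", sprintf("NR_%06d", acc_num),
                      sprintf("NM_%06d", acc_num))
  genes <- data.frame(accession = accession, chrom = picked$chrom,
                      strand = strand, tx_start = tx_start, tx_end = tx_end,
                      gene_symbol = sprintf("Gene%d", acc_num),
                      stringsAsFactors = FALSE)
  # duplicate transcripts: same exact TSS as a randomly chosen eligible
  # gene, different length (still coding and > 2 kb)
  good_idx <- which(kind == "good")
  if (n_dup > 0) {
    parent <- sample(good_idx, n_dup, replace = n_dup > length(good_idx))
    dlen <- len[parent] + 1500
    dstart <- ifelse(strand[parent] == "+", tss[parent],
                     tss[parent] + 1 - dlen)
    dend <- ifelse(strand[parent] == "+", tss[parent] + dlen,
                   tss[parent] + 1)
    dup <- data.frame(accession = sprintf("NM_%06d", n_slots_needed + seq_len(n_dup)),
                      chrom = picked$chrom[parent], strand = strand[parent],
                      tx_start = dstart, tx_end = dend,
                      gene_symbol = genes$gene_symbol[parent],
                      stringsAsFactors = FALSE)
    genes <- rbind(genes, dup)
  }
  ord <- order(genes$chrom, genes$tx_start, genes$accession)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL

  truth <- data.frame(
    name = sprintf("%s:%d:%s", picked$chrom[good_idx],
                   as.integer(tss[good_idx]), strand[good_idx]),
    chrom = picked$chrom[good_idx], strand = strand[good_idx],
    tss = tss[good_idx], gene = accession[good_idx],
    stringsAsFactors = FALSE
  )
  truth$class <- sample_simplex_exact(config$class_proportions, nrow(truth))
  truth$cluster <- sample_simplex_exact(config$cluster_proportions,
                                        nrow(truth))
  truth$up_effect <- config$kd_effect_log2[truth$cluster, "up"]
  truth$down_effect <- config$kd_effect_log2[truth$cluster, "down"]
  truth <- truth[order(truth$chrom, truth$tss), , drop = FALSE]
  rownames(truth) <- NULL
  list(genes = genes, truth = truth)
}

# Realize a label simplex by exact counts (largest-remainder rounding)
# and a random permutation.  Exact realization keeps quantile-based
# thresholds in the gap between label populations, mirroring a fixed
# catalog partition rather than a binomial draw around it.
sample_simplex_exact <- function(props, n) {
  counts <- floor(props * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(props * n - floor(props * n), decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  sample(rep(names(props), counts))
}

# Expected (noise-free) density of one track kind over the binned
# promoter neighbourhoods.  Returns data.frame chrom/start/end/density.
sim_expected_bins <- function(config, truth, kind = c("brg1", "atac",
                                                      "h3k4me3", "h3k27me3"),
                              condition = c("control", "kd")) {
  kind <- match.arg(kind)
  condition <- match.arg(condition)
  bw <- config$noise$bin_bp
  flank <- config$support_flank_bp
  np <- nrow(truth)
  if (kind %in% c("h3k4me3", "h3k27me3")) {
    # plateau tracks are binned on the window itself (1500 bp is an
    # exact multiple of the bin width), so noise-free window means hit
    # the configured per-class level exactly on either strand
    win <- promoter_window(truth)   # -500/+1000 oriented window
    wlen <- win$end[1] - win$start[1]
    if (wlen %% bw != 0) {
      stop("promoter window length must be a multiple of noise$bin_bp",
           call. = FALSE)
    }
    nb <- as.integer(wlen / bw)
    p <- rep(seq_len(np), each = nb)
    start <- win$start[p] + rep(seq(0, wlen - bw, by = bw), np)
    level <- config$mark_levels[[kind]][truth$class[p]]
    dens <- config$background_density + level
    return(data.frame(chrom = truth$chrom[p], start = start,
                      end = start + bw, density = unname(dens),
                      stringsAsFactors = FALSE))
  }
  nb <- as.integer(2 * flank / bw)
  offs <- seq(-flank, flank - bw, by = bw)
  p <- rep(seq_len(np), each = nb)
  start <- truth$tss[p] + rep(offs, np)
  mid <- start + bw / 2
  s <- ifelse(truth$strand[p] == "+", 1, -1)
  dens <- rep(config$background_density, length(start))
  if (kind == "atac") {
    amp <- config$atac$amplitude[truth$class[p]]
    dens <- dens + amp * exp(-(mid - truth$tss[p])^2 /
                               (2 * config$atac$sigma^2))
  } else {
    arch <- config$brg1_architecture
    amp <- arch$amplitude[truth$class[p]]
    c_up <- truth$tss[p] + s * arch$upstream_offset
    c_dn <- truth$tss[p] + s * arch$downstream_offset
    m_up <- if (condition == "kd") 2^truth$up_effect[p] else 1
    m_dn <- if (condition == "kd") 2^truth$down_effect[p] else 1
    dens <- dens +
      amp * m_up * exp(-(mid - c_up)^2 / (2 * arch$sigma^2)) +
      amp * m_dn * exp(-(mid - c_dn)^2 / (2 * arch$sigma^2))
  }
  data.frame(chrom = truth$chrom[p], start = start, end = start + bw,
             density = unname(dens), stringsAsFactors = FALSE)
}

sim_track_names <- function() {
  c("brg1_control", "brg1_kd", "atac_control", "atac_kd",
    "h3k4me3_control", "h3k4me3_kd", "h3k27me3_control", "h3k27me3_kd")
}

#' Generate synthetic coverage tracks
#'
#' Builds the expected per-base density of each track -- per-class
#' Gaussian remodeler bumps at the -1/+1 nucleosome offsets (with
#' knockdown multiplying the bump amplitudes by `2^effect`), an NFR
#' accessibility bump at the TSS, and per-class mark plateaus over the
#' -500/+1000 window -- then samples fragment counts per bin
#' (`Poisson(density x bin_bp x depth)`) and stores counts/bin width as
#' run values.  With noise disabled the runs carry the exact expected
#' density.  The truth table's `expected_mass` attribute records each
#' track's noise-free total mass (times depth when sampling), which
#' recovery analyses can normalize against.
#'
#' @param config a [synthetic_config()].
#' @param truth truth table from [generate_gene_table()].
#' @return Named list of eight [signal_track()]s
#'   (`brg1_control`, `brg1_kd`, `atac_control`, `atac_kd`,
#'   `h3k4me3_control`, `h3k4me3_kd`, `h3k27me3_control`,
#'   `h3k27me3_kd`) with an `expected_mass` attribute (named numeric).
#' @export
generate_tracks <- function(config, truth) {
  set.seed(config$seed + 1L)
  bw <- config$noise$bin_bp
  depth <- config$noise$depth
  out <- list()
  expected_mass <- numeric()
  for (nm in sim_track_names()) {
    kind <- sub("_(control|kd)$", "", nm)
    condition <- sub("^.*_", "", nm)
    bins <- sim_expected_bins(config, truth, kind, condition)
    if (config$noise$enabled) {
      counts <- rpois(nrow(bins), bins$density * bw * depth)
      value <- counts / bw
      expected_mass[nm] <- sum(bins$density * bw) * depth
    } else {
      value <- bins$density
      expected_mass[nm] <- sum(bins$density * bw)
    }
    keep <- value > 0
    out[[nm]] <- signal_track(data.frame(
      chrom = bins$chrom[keep], start = bins$start[keep],
      end = bins$end[keep], value = value[keep], stringsAsFactors = FALSE))
  }
  attr(out, "expected_mass") <- expected_mass
  out
}

#' Generate matched synthetic peak sets
#'
#' One remodeler (BRG1-like) peak per simulated occupancy bump (two per
#' promoter, spanning bump centre +/- 2 sigma) and one accessibility
#' (ATAC-like) peak per NFR, at the true locations; optional decoy
#' remodeler peaks are placed in gene deserts, beyond assignment range
#' of any accessibility peak.
#'
#' @param truth truth table from [generate_gene_table()].
#' @param config a [synthetic_config()].
#' @return List with peak data.frames `brg1` and `atac`.
#' @export
generate_peaks <- function(truth, config) {
  arch <- config$brg1_architecture
  s <- ifelse(truth$strand == "+", 1, -1)
  c_up <- truth$tss + s * arch$upstream_offset
  c_dn <- truth$tss + s * arch$downstream_offset
  w <- 2 * arch$sigma
  brg1 <- data.frame(
    chrom = rep(truth$chrom, 2),
    start = c(c_up - w, c_dn - w),
    end = c(c_up + w, c_dn + w),
    name = c(sprintf("brg1_up_%d", seq_len(nrow(truth))),
             sprintf("brg1_dn_%d", seq_len(nrow(truth)))),
    score = rep(unname(arch$amplitude[truth$class]), 2),
    stringsAsFactors = FALSE
  )
  wa <- 2 * config$atac$sigma
  atac <- data.frame(
    chrom = truth$chrom, start = truth$tss - wa, end = truth$tss + wa,
    name = sprintf("atac_%d", seq_len(nrow(truth))),
    score = unname(config$atac$amplitude[truth$class]),
    stringsAsFactors = FALSE
  )
  if (config$decoy_peaks > 0) {
    sizes <- sim_chrom_sizes(config)
    decoy <- do.call(rbind, lapply(names(sizes), function(ch) {
      pos <- sizes[[ch]] - 5000 - (seq_len(config$decoy_peaks) - 1) * 1000
      data.frame(chrom = ch, start = pos, end = pos + 200,
                 name = sprintf("decoy_%s_%d", ch,
                                seq_len(config$decoy_peaks)),
                 score = 1, stringsAsFactors = FALSE)
    }))
    brg1 <- rbind(brg1, decoy)
  }
  brg1 <- brg1[order(brg1$chrom, brg1$start), , drop = FALSE]
  atac <- atac[order(atac$chrom, atac$start), , drop = FALSE]
  rownames(brg1) <- rownames(atac) <- NULL
  list(brg1 = brg1, atac = atac)
}

#' Generate a synthetic expression table
#'
#' One record per eligible promoter (keyed by its representative gene
#' accession).  Promoters with an injected occupancy loss become
#' down-regulated DEGs with probability `expression$p_down`
#' (fold change well below 1/1.5, p below 0.05); a small fraction of
#' other promoters become up DEGs; the rest stay near fold change 1
#' with non-significant p.  The truth table gains a `deg_direction`
#' column.
#'
#' @param truth truth table from [generate_gene_table()].
#' @param config a [synthetic_config()].
#' @return List with `expression` (see [read_expression_table()]) and
#'   the augmented `truth`.
#' @export
generate_expression <- function(truth, config) {
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  lost <- truth$up_effect < 0 | truth$down_effect < 0
  direction <- rep("NONE", n)
  direction[lost & runif(n) < config$expression$p_down] <- "DOWN"
  direction[direction == "NONE" & runif(n) < config$expression$p_up] <- "UP"
  fc <- 2^rnorm(n, 0, 0.1)
  fc[direction == "DOWN"] <- pmin(2^rnorm(sum(direction == "DOWN"), -1.2, 0.25),
                                  1 / 1.6)
  fc[direction == "UP"] <- pmax(2^rnorm(sum(direction == "UP"), 1.2, 0.25),
                                1.6)
  p <- runif(n, 0.1, 1)
  p[direction != "NONE"] <- runif(sum(direction != "NONE"), 1e-4, 0.04)
  value_ctrl <- 10 * 2^rnorm(n, 0, 0.5)
  expression <- data.frame(gene = truth$gene, value_ctrl = value_ctrl,
                           value_kd = value_ctrl * fc, fold_change = fc,
                           p_value = p, stringsAsFactors = FALSE)
  truth$deg_direction <- direction
  list(expression = expression, truth = truth)
}

#' Simulate a complete synthetic chromatin study
#'
#' Runs [generate_gene_table()], [generate_tracks()],
#' [generate_peaks()] and [generate_expression()] under one seed.
#'
#' @param config a [synthetic_config()].
#' @return List of class `synthetic_study`: `genes`, `truth`, `tracks`
#'   (8 signal tracks with `expected_mass` attribute), `peaks`
#'   (`brg1`, `atac`), `expression`, `chrom_sizes`, `config`.
#' @export
simulate_chromatin <- function(config = synthetic_config()) {
  gt <- generate_gene_table(config)
  tracks <- generate_tracks(config, gt$truth)
  peaks <- generate_peaks(gt$truth, config)
  ex <- generate_expression(gt$truth, config)
  structure(list(genes = gt$genes, truth = ex$truth, tracks = tracks,
                 peaks = peaks, expression = ex$expression,
                 chrom_sizes = sim_chrom_sizes(config), config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic chromatin study: %d genes, %d promoters, %d tracks\n",
              nrow(x$genes), nrow(x$truth), length(x$tracks)))
  cat("promoter classes:", paste(sprintf("%s=%d", names(table(x$truth$class)),
                                         table(x$truth$class)),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Emits the refGene-dialect gene table, eight bedGraph tracks, two BED
#' peak sets, the expression table and the truth table under `dir`.
#'
#' @param study a [simulate_chromatin()] result.
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genes = file.path(dir, "genes.refgene.txt"))
  write_gene_table(study$genes, paths$genes)
  for (nm in names(study$tracks)) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".bedgraph"))
    write_bedgraph(study$tracks[[nm]], paths[[nm]])
  }
  for (nm in names(study$peaks)) {
    key <- paste0(nm, "_peaks")
    paths[[key]] <- file.path(dir, paste0(nm, "_peaks.bed"))
    write_bed(study$peaks[[nm]], paths[[key]])
  }
  paths$expression <- file.path(dir, "expression.tsv")
  utils::write.table(study$expression, paths$expression, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(study$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
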