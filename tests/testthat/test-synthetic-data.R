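small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_chroms = 2, chrom_length_bp = 1.5e6,
                   n_genes = 150, ...)
}

test_that("generation is byte-deterministic under a fixed seed", {
  s1 <- simulate_chromatin(small_config(seed = 5))
  s2 <- simulate_chromatin(small_config(seed = 5))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$expression, s2$expression)
  s3 <- simulate_chromatin(small_config(seed = 6))
  expect_false(identical(s1$tracks$brg1_control, s3$tracks$brg1_control))
})

test_that("configured record fractions are realized exactly", {
  cfg <- small_config(seed = 2, fraction_noncoding = 0.2)
  gt <- generate_gene_table(cfg)
  expect_equal(nrow(gt$genes), 150)
  expect_equal(sum(startsWith(gt$genes$accession, "NR_")), 30)
  len <- gt$genes$tx_end - gt$genes$tx_start
  expect_equal(sum(startsWith(gt$genes$accession, "NM_") & len < 2000),
               round(0.1 * 150))
  # with no duplicate TSSs every eligible gene is its own promoter
  cfg0 <- small_config(seed = 3, fraction_duplicate_tss = 0)
  gt0 <- generate_gene_table(cfg0)
  cat0 <- build_promoter_catalog(gt0$genes)
  expect_equal(nrow(cat0), nrow(gt0$truth))
  expect_true(all(cat0$n_members == 1))
  # duplicates merge into their parent promoters
  cat1 <- build_promoter_catalog(gt$genes)
  expect_equal(nrow(cat1), nrow(gt$truth))
  expect_equal(sort(cat1$name), sort(gt$truth$name))
  expect_error(synthetic_config(fraction_noncoding = 0.6, fraction_short = 0.5),
               "fractions")
})

test_that("noise-free tracks reproduce the configured signal exactly", {
  cfg <- small_config(seed = 4, noise = list(enabled = FALSE, depth = 1,
                                             bin_bp = 25))
  gt <- generate_gene_table(cfg)
  tracks <- generate_tracks(cfg, gt$truth)
  win <- promoter_window(gt$truth)
  k4 <- window_intensity(tracks$h3k4me3_control, win)
  low <- gt$truth$class == "H3K4me3_LOW"
  expect_equal(k4[low], rep(0.5, sum(low)), tolerance = 1e-12)
  only <- gt$truth$class == "H3K4me3_ONLY"
  expect_equal(k4[only], rep(8, sum(only)), tolerance = 1e-12)
  expect_equal(unname(track_mass(tracks$h3k4me3_control)),
               unname(attr(tracks, "expected_mass")[["h3k4me3_control"]]),
               tolerance = 1e-9)

  # a Cluster2 promoter shows (DECREASED, UNCHANGED) at default offsets
  c2 <- which(gt$truth$cluster == "Cluster2" &
                gt$truth$class == "H3K4me3_ONLY")[1]
  tab <- cluster_tss(gt$truth[c2, , drop = FALSE], tracks$brg1_control,
                     tracks$brg1_kd)
  expect_equal(as.character(tab$up_call), "DECREASED")
  expect_equal(as.character(tab$down_call), "UNCHANGED")
  expect_equal(as.character(tab$cluster), "Cluster2")
})

test_that("sequencing depth scales total mass proportionally", {
  cfg1 <- small_config(seed = 7)
  cfg2 <- small_config(seed = 7, noise = list(enabled = TRUE, depth = 2,
                                              bin_bp = 25))
  t1 <- generate_tracks(cfg1, generate_gene_table(cfg1)$truth)
  t2 <- generate_tracks(cfg2, generate_gene_table(cfg2)$truth)
  em1 <- attr(t1, "expected_mass"); em2 <- attr(t2, "expected_mass")
  expect_equal(unname(em2), unname(2 * em1))
  r <- track_mass(t2$brg1_control) / track_mass(t1$brg1_control)
  expect_lt(abs(r - 2), 0.05)
})

test_that("peak sets mirror the simulated architecture", {
  cfg <- small_config(seed = 8)
  gt <- generate_gene_table(cfg)
  pk <- generate_peaks(gt$truth, cfg)
  n <- nrow(gt$truth)
  expect_equal(nrow(pk$brg1), 2 * n)
  expect_equal(nrow(pk$atac), n)
  # every occupancy peak has an accessibility peak within 2 kb
  asg <- assign_nearby(pk$brg1, pk$atac, 2000)
  expect_setequal(unique(asg$anchor), pk$brg1$name)

  # desert decoys fall out of the nearby assignment
  cfgd <- small_config(seed = 8, decoy_peaks = 3)
  pkd <- generate_peaks(generate_gene_table(cfgd)$truth, cfgd)
  expect_equal(nrow(pkd$brg1), 2 * n + 2 * 3)
  asgd <- assign_nearby(pkd$brg1, pkd$atac, 2000)
  expect_false(any(grepl("^decoy", asgd$anchor)))
})

test_that("study files round-trip through their plain-text formats", {
  st <- simulate_chromatin(small_config(seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_study(st, dir)
  expect_equal(read_gene_table(paths$genes), st$genes)
  back <- read_bedgraph(paths$brg1_control)
  expect_equal(as.data.frame(back), as.data.frame(st$tracks$brg1_control))
  expect_equal(read_bed(paths$brg1_peaks), st$peaks$brg1)
  expect_equal(read_expression_table(paths$expression)$fold_change,
               st$expression$fold_change, tolerance = 1e-6)
})
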