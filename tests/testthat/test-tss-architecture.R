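test_that("subregions sit at their offsets and mirror on the minus strand", {
  p_plus <- data.frame(chrom = "chr1", tss = 10000, strand = "+")
  r <- define_regions(p_plus)
  expect_equal(r$upstream, data.frame(chrom = "chr1", start = 9700, end = 9900))
  expect_equal(r$center, data.frame(chrom = "chr1", start = 9900, end = 10100))
  expect_equal(r$downstream,
               data.frame(chrom = "chr1", start = 10100, end = 10300))

  p_minus <- data.frame(chrom = "chr1", tss = 10000, strand = "-")
  rm_ <- define_regions(p_minus)
  # mirror image about the TSS base: upstream lies at higher coordinates
  expect_equal(rm_$upstream,
               data.frame(chrom = "chr1", start = 10101, end = 10301))
  expect_equal(rm_$center,
               data.frame(chrom = "chr1", start = 9901, end = 10101))
  expect_equal(rm_$downstream,
               data.frame(chrom = "chr1", start = 9701, end = 9901))
})

test_that("region triplets are disjoint and ordered for random offsets", {
  set.seed(31)
  for (i in 1:10) {
    cuts <- sort(sample(-600:600, 4))
    cuts <- cuts[c(1, 2, 2, 3, 3, 4)]
    if (cuts[1] == cuts[2] || cuts[3] == cuts[4] || cuts[5] == cuts[6]) next
    off <- region_offsets(upstream = cuts[1:2], center = cuts[3:4],
                          downstream = cuts[5:6])
    for (strand in c("+", "-")) {
      r <- define_regions(data.frame(chrom = "c", tss = 5000, strand = strand),
                          off)
      iv <- rbind(r$upstream, r$center, r$downstream)
      iv <- iv[order(iv$start), ]
      expect_true(all(iv$start[-1] >= iv$end[-3]))
    }
  }
  expect_error(region_offsets(upstream = c(-100, -300)), "to > from")
  expect_error(region_offsets(upstream = c(-300, 50)), "disjoint")
})

test_that("fold-change calls use the 1.5-fold rule symmetrically", {
  p0 <- diff_params(pseudocount = 0)
  expect_equal(as.character(call_change(10, 6, p0)), "DECREASED")   # 1.667x
  expect_equal(as.character(call_change(10, 10, p0)), "UNCHANGED")
  expect_equal(as.character(call_change(10, 16, p0)), "INCREASED")  # 1.6x
  expect_equal(as.character(call_change(10, 15, p0)), "INCREASED")  # boundary
  expect_equal(as.character(call_change(15, 10, p0)), "DECREASED")
  expect_equal(as.character(call_change(10, 14.9, p0)), "UNCHANGED")
})

test_that("scaling both tracks equally leaves calls unchanged", {
  set.seed(32)
  p0 <- diff_params(pseudocount = 0)
  ctrl <- runif(50, 0.1, 20)
  kd <- runif(50, 0.1, 20)
  base <- call_change(ctrl, kd, p0)
  for (f in c(0.01, 3, 1e4)) {
    expect_equal(call_change(f * ctrl, f * kd, p0), base)
  }
})

test_that("the cluster taxonomy maps change-call pairs deterministically", {
  expect_equal(as.character(assign_cluster("DECREASED", "DECREASED")), "Cluster1")
  expect_equal(as.character(assign_cluster("DECREASED", "UNCHANGED")), "Cluster2")
  expect_equal(as.character(assign_cluster("UNCHANGED", "DECREASED")), "Cluster3")
  expect_equal(as.character(assign_cluster("DECREASED", "INCREASED")), "Cluster4")
  expect_equal(as.character(assign_cluster("INCREASED", "DECREASED")), "Cluster5")
  expect_equal(as.character(assign_cluster("UNCHANGED", "UNCHANGED")), "UNCLUSTERED")
  expect_equal(as.character(assign_cluster("INCREASED", "INCREASED")), "UNCLUSTERED")

  # swapping up and down exchanges 2<->3 and 4<->5, fixes Cluster1
  calls <- c("DECREASED", "UNCHANGED", "INCREASED")
  grid <- expand.grid(up = calls, down = calls, stringsAsFactors = FALSE)
  a <- as.character(assign_cluster(grid$up, grid$down))
  b <- as.character(assign_cluster(grid$down, grid$up))
  swap <- c(Cluster1 = "Cluster1", Cluster2 = "Cluster3",
            Cluster3 = "Cluster2", Cluster4 = "Cluster5",
            Cluster5 = "Cluster4", UNCLUSTERED = "UNCLUSTERED")
  expect_equal(unname(swap[a]), b)
})

test_that("decreased-TSS selection keeps any TSS with >= 1 decreased flank", {
  catalog <- data.frame(name = c("a", "b", "c"), chrom = "chr1",
                        strand = "+", tss = c(10000, 30000, 50000),
                        stringsAsFactors = FALSE)
  # control: value 10 on both flanks of every TSS
  flanks <- function(tss) c(tss - 300, tss + 100)
  ctrl <- make_track("chr1",
                     unlist(lapply(catalog$tss, flanks)),
                     unlist(lapply(catalog$tss, flanks)) + 200,
                     rep(10, 6))
  # kd: a decreased upstream only; b unchanged; c increased both
  kd_vals <- c(5, 10, 10, 10, 20, 20)
  kd <- make_track("chr1",
                   unlist(lapply(catalog$tss, flanks)),
                   unlist(lapply(catalog$tss, flanks)) + 200,
                   kd_vals)
  sel <- select_decreased_tss(catalog, ctrl, kd,
                              params = diff_params(pseudocount = 0))
  expect_equal(sel$name, "a")
  expect_equal(as.character(sel$cluster), "Cluster2")
  # every selected TSS carries a definite cluster, never UNCLUSTERED
  expect_false(any(sel$cluster == "UNCLUSTERED"))
})
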