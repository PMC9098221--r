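test_that("peak merging coalesces overlapping and bookended intervals", {
  a <- make_peaks("chr1", 0, 10)
  b <- make_peaks("chr1", 5, 15)
  expect_equal(merge_peaks(a, b)[, c("start", "end")],
               data.frame(start = 0, end = 15))
  c_ <- make_peaks("chr1", 10, 20)
  expect_equal(merge_peaks(a, c_)[, c("start", "end")],
               data.frame(start = 0, end = 20))
  x <- make_peaks("chr1", c(0, 100), c(50, 200))
  expect_equal(merge_peaks(x, x)[, 1:3], merge_peaks(x)[, 1:3])
  expect_equal(merge_peaks(x, a)[, 1:3], merge_peaks(a, x)[, 1:3])
  expect_match(merge_peaks(x)$name, "^merged_")
})

test_that("merged peaks are sorted, disjoint, and mass-bounded", {
  set.seed(41)
  for (i in 1:5) {
    n <- 40
    pk <- make_peaks(sample(c("chr1", "chr2"), n, TRUE),
                     start <- sample.int(5000, n),
                     start + sample.int(400, n))
    m <- merge_peaks(pk)
    ord <- order(m$chrom, m$start)
    expect_equal(ord, seq_len(nrow(m)))
    same <- m$chrom[-1] == m$chrom[-nrow(m)]
    expect_true(all(!same | m$start[-1] > m$end[-nrow(m)]))  # gaps > 0
    expect_lte(sum(m$end - m$start), sum(pk$end - pk$start))
  }
})

test_that("nearby assignment keeps duplicates and excludes distant anchors", {
  anchors <- make_peaks("chr1", 1000, 1500, "A")
  q1 <- make_peaks("chr1", 3000, 3100, "q1")
  out <- assign_nearby(anchors, q1, max_dist = 2000)
  expect_equal(nrow(out), 1)
  expect_equal(out$edge_distance, 1500)

  q_far <- make_peaks("chr1", 4000, 4100, "far")  # gap 2500
  expect_equal(nrow(assign_nearby(anchors, q_far, 2000)), 0)

  # one anchor, two in-range queries -> two rows, no deduplication
  qq <- make_peaks("chr1", c(1600, 2000), c(1700, 2100), c("x", "y"))
  out2 <- assign_nearby(anchors, qq, 2000)
  expect_equal(nrow(out2), 2)
  expect_equal(unique(out2$anchor), "A")

  # unique-query mode keeps only the closest anchor per query
  two_anchors <- make_peaks("chr1", c(0, 900), c(100, 1000), c("A", "B"))
  q <- make_peaks("chr1", 1200, 1300, "q")
  u <- assign_nearby(two_anchors, q, 2000, unique_query = TRUE)
  expect_equal(u$anchor, "B")
  expect_equal(nrow(assign_nearby(two_anchors, q, 2000)), 2)
})

test_that("nearby assignment matches the all-pairs brute-force scan", {
  set.seed(42)
  for (i in 1:4) {
    na_ <- sample(20:60, 1); nq <- sample(20:60, 1)
    anchors <- make_peaks(sample(c("chr1", "chr2"), na_, TRUE),
                          s <- sample.int(20000, na_), s + sample.int(300, na_),
                          sprintf("a%d", 1:na_))
    queries <- make_peaks(sample(c("chr1", "chr2"), nq, TRUE),
                          s2 <- sample.int(20000, nq), s2 + sample.int(300, nq),
                          sprintf("q%d", 1:nq))
    got <- assign_nearby(anchors, queries, 1000)
    want <- brute_nearby(anchors, queries, 1000)
    key <- function(d) sort(sprintf("%s|%s|%g", d$anchor, d$query,
                                    d$edge_distance))
    expect_equal(key(got), key(want))
  }
})

test_that("high/low splits are equal with the larger low group on odd N", {
  pk <- make_peaks("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350))
  sp <- split_high_low(pk, c(4, 3, 2, 1))
  expect_equal(sp$high$key, c(4, 3))
  expect_equal(sp$low$key, c(2, 1))

  pk5 <- make_peaks("chr1", seq(0, 400, 100), seq(50, 450, 100))
  sp5 <- split_high_low(pk5, 5:1)
  expect_equal(nrow(sp5$high), 2)
  expect_equal(nrow(sp5$low), 3)

  # deterministic position tie-break and partition invariants
  set.seed(43)
  for (n in c(7, 20, 33)) {
    pk_n <- make_peaks("chr1", s <- sample.int(1e5, n), s + 100)
    keys <- sample(rep(1:3, length.out = n))
    s1 <- split_high_low(pk_n, keys)
    # row order of the input must not matter (position tie-break)
    perm <- sample(n)
    s2 <- split_high_low(pk_n[perm, ], keys[perm])
    expect_equal(s1$high$name, s2$high$name)
    expect_equal(nrow(s1$high) + nrow(s1$low), n)
    expect_true((nrow(s1$low) - nrow(s1$high)) %in% c(0, 1))
    expect_gte(min(s1$high$key), max(s1$low$key))
  }
  expect_error(split_high_low(pk[0, ], numeric()), "empty")
})

test_that("annotation enrichment uses midpoint membership and binomial tails", {
  set.seed(44)
  peaks <- make_peaks("chr1", s <- seq(0, 99000, 1000), s + 100)  # 100 peaks
  genome <- 1e6
  # annotation covering 10% of the genome containing exactly 10 midpoints
  ann10 <- data.frame(chrom = "chr1", start = 0, end = 1e5)
  res <- annotation_enrichment(peaks, list(ten_pct = ann10), genome)
  # observed 100 here; craft the printed example directly instead:
  expect_equal(res$observed, 100)

  obs_eq <- annotation_enrichment(
    make_peaks("chr1", 0:99 * 10000, 0:99 * 10000 + 10),
    list(a = data.frame(chrom = "chr1", start = 0, end = 1e5)), 1e6)
  expect_equal(obs_eq$observed, 10)
  expect_equal(obs_eq$log2_enrichment, 0)  # log2(10.5 / 10.5)

  # enrichment and depletion arithmetic
  expect_equal(log2((40 + 0.5) / (10 + 0.5)), 1.947, tolerance = 1e-3)
  dep <- annotation_enrichment(
    make_peaks("chr1", 5e5 + 0:99 * 100, 5e5 + 0:99 * 100 + 10),
    list(a = data.frame(chrom = "chr1", start = 0, end = 1e5)), 1e6)
  expect_equal(dep$observed, 0)
  expect_equal(dep$log2_enrichment, log2(0.5 / 10.5))
  expect_equal(dep$p_value, pbinom(0, 100, 0.1))
  expect_true(all(dep$p_value > 0 & dep$p_value <= 1))

  expect_warning(
    out <- annotation_enrichment(peaks,
                                 list(bad = ann10[0, ], ok = ann10), genome),
    "zero length")
  expect_equal(out$annotation, "ok")
})
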