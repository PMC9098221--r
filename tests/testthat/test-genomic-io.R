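test_that("read_bed parses coordinates, names and scores", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# comment", "track name=x",
               "chr1\t100\t200\tp1\t7.5",
               "chr1\t300\t400"), f)
  pk <- read_bed(f)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$start, c(100, 300))
  expect_equal(pk$end, c(200, 400))
  expect_equal(pk$name[1], "p1")
  expect_equal(pk$score[1], 7.5)
  expect_match(pk$name[2], "^peak_")

  writeLines(character(), f)
  expect_equal(nrow(read_bed(f)), 0)

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t0\t10\ta", "chr1\tfoo\t10"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("read_bedgraph validates runs and computes mass", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t100\t2.0", f)
  tr <- read_bedgraph(f)
  expect_equal(track_mass(tr), 200)

  writeLines(c("chr1\t0\t50\t1", "chr1\t50\t100\t1"), f)
  tr <- read_bedgraph(f)
  expect_equal(track_mass(tr), 100)
  expect_equal(nrow(tr), 2)  # bookended runs stay unmerged

  writeLines(c("chr1\t0\t60\t1", "chr1\t50\t100\t1"), f)
  expect_error(read_bedgraph(f), "overlap")
  writeLines("chr1\t0\t10\t-1", f)
  expect_error(read_bedgraph(f), "negative")
})

test_that("bedgraph total mass matches brute-force per-base summation", {
  set.seed(11)
  for (i in 1:5) {
    tr <- random_track(10000, n_runs = 25)
    dense <- dense_intensity(tr, "chr1", 0, 10000) * 10000
    expect_equal(track_mass(tr), dense, tolerance = 1e-9)
  }
})

test_that("gene tables read identically with and without the bin column", {
  f <- withr::local_tempfile()
  writeLines("NM_001\tchr1\t+\t1000\t5000\tFoo", f)
  g1 <- read_gene_table(f)
  writeLines("585\tNM_001\tchr1\t+\t1000\t5000\tFoo", f)
  g2 <- read_gene_table(f, has_bin_column = TRUE)
  expect_identical(g1, g2)
  expect_equal(g1$tx_start, 1000)
  expect_equal(g1$strand, "+")

  writeLines("NM_001\tchr1\t.\t1000\t5000", f)
  expect_error(read_gene_table(f), "strand")
})

test_that("normalize_track rescales to the target mass and is idempotent", {
  tr <- make_track("chr1", c(0, 1000), c(1000, 2000), c(1500, 500))
  expect_equal(track_mass(tr), 2e6)
  nt <- normalize_track(tr)
  expect_equal(nt$value, tr$value / 2)
  expect_equal(track_mass(nt), 1e6, tolerance = 1e-9)

  # identity at target mass, idempotence
  expect_equal(normalize_track(nt)$value, nt$value, tolerance = 1e-12)
  tr2 <- make_track("chr1", 0, 100, 3)
  n1 <- normalize_track(tr2, 5000)
  expect_equal(normalize_track(n1, 5000)$value, n1$value, tolerance = 1e-12)

  empty <- signal_track(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), value = numeric()))
  expect_error(normalize_track(empty), "zero total mass")
})

test_that("write/read round-trips are the identity", {
  f <- withr::local_tempfile()
  tr <- make_track("chr1", c(0, 100, 500), c(50, 300, 900), c(1.25, 3, 0.125))
  write_bedgraph(tr, f)
  back <- read_bedgraph(f)
  expect_equal(as.data.frame(back), as.data.frame(tr))

  # zero-valued runs are dropped on write; equal under the value-0 convention
  trz <- make_track("chr1", c(0, 100), c(50, 200), c(2, 0))
  write_bedgraph(trz, f)
  expect_equal(nrow(read_bedgraph(f)), 1)
  expect_equal(window_intensity(read_bedgraph(f),
                                data.frame(chrom = "chr1", start = 0, end = 200)),
               window_intensity(trz,
                                data.frame(chrom = "chr1", start = 0, end = 200)))

  pk <- make_peaks("chr1", c(10, 500), c(200, 800), c("a", "b"), c(1.5, 2))
  write_bed(pk, f)
  expect_equal(read_bed(f), pk)

  g <- small_gene_table()
  write_gene_table(g, f)
  expect_equal(read_gene_table(f), g)
})

test_that("signal_track rejects invalid run tables", {
  expect_error(make_track("chr1", 10, 10, 1), "end <= start")
  expect_error(make_track("chr1", c(0, 5), c(10, 20), c(1, 1)), "overlap")
  expect_error(make_track("chr1", 0, 10, -2), "non-negative")
  expect_error(make_track("", 0, 10, 1), "chromosome")
})
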