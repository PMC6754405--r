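test_that("BED reading preserves 0-based half-open coordinates and round-trips", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t150\t300", "chr2\t10\t20"), path)
  gr <- read_bed(path)
  expect_equal(GenomicRanges::start(gr), c(1, 151, 11))   # 1-based internal
  expect_equal(GenomicRanges::end(gr), c(100, 300, 20))
  out <- tempfile(fileext = ".bed")
  write_bed(gr, out)
  expect_identical(readLines(out), readLines(path))
  # BED6 with strand survives a round trip
  p6 <- tempfile(fileext = ".bed")
  writeLines("chr1\t5\t50\tpeak1\t7\t-", p6)
  g6 <- read_bed(p6)
  expect_identical(as.character(GenomicRanges::strand(g6)), "-")
  o6 <- tempfile(fileext = ".bed")
  write_bed(g6, o6)
  expect_identical(readLines(o6), readLines(p6))
})

test_that("malformed BED lines are rejected with their line number", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t200\t200"), path)
  expect_error(read_bed(path), "line 2.*start >= end")
  writeLines(c("chr1\t0\t100", "chr1\tx\t300"), path)
  expect_error(read_bed(path), "line 2.*non-numeric")
  writeLines("chr1\t100", path)
  expect_error(read_bed(path), "line 1.*fewer than 3")
  # chromosome filter applies at read time
  writeLines(c("chr1\t0\t10", "chrM\t0\t10"), path)
  expect_identical(length(read_bed(path, drop_chroms = "chrM")), 1L)
})

test_that("merging coalesces overlaps and 0-gap adjacency", {
  a <- mat_to_gr(rbind(c(0, 10)))
  b <- mat_to_gr(rbind(c(5, 15)))
  m <- merge_set(a, b)
  expect_equal(gr_to_mat(m), cbind(0, 15), ignore_attr = TRUE)
  adj <- merge_set(mat_to_gr(rbind(c(0, 10), c(10, 20))))
  expect_equal(gr_to_mat(adj), cbind(0, 20), ignore_attr = TRUE)
  dis <- merge_set(mat_to_gr(rbind(c(0, 10))), mat_to_gr(rbind(c(30, 40))))
  expect_identical(length(dis), 2L)
  # random sets vs the per-bp membership oracle: exact
  set.seed(99)
  for (i in 1:25) {
    g <- 10000
    ma <- random_intervals(30, g); mb <- random_intervals(30, g)
    got <- gr_to_mat(merge_set(mat_to_gr(ma), mat_to_gr(mb)))
    want <- oracle_merge(list(ma, mb), g)
    expect_equal(unname(got), unname(want))
  }
})

test_that("overlap metrics agree exactly with per-bp brute force", {
  a <- mat_to_gr(rbind(c(0, 10), c(20, 30)))
  b <- mat_to_gr(rbind(c(9, 12)))
  expect_equal(peak_intersect_fraction(a, b), 50)
  expect_equal(peak_intersect_fraction(a, a), 100)
  expect_equal(peak_intersect_fraction(mat_to_gr(rbind(c(0, 100))),
                                       mat_to_gr(rbind(c(0, 50)))), 100)
  expect_equal(bp_coverage_fraction(mat_to_gr(rbind(c(0, 100))),
                                    mat_to_gr(rbind(c(0, 50)))), 50)
  # adjacency is not overlap
  expect_equal(peak_intersect_fraction(mat_to_gr(rbind(c(0, 10))),
                                       mat_to_gr(rbind(c(10, 20)))), 0)
  # 5 reads on a 500 bp peak -> 1 read / 100 bp
  peak <- mat_to_gr(rbind(c(0, 500)))
  reads <- mat_to_gr(cbind(seq(0, 400, by = 100), seq(50, 450, by = 100)))
  expect_equal(reads_per_100bp(peak, reads), 1)
  expect_equal(reads_per_100bp(peak, mat_to_gr(rbind(c(600, 650)))), 0)

  set.seed(123)
  for (i in 1:30) {
    g <- 10000
    ma <- random_intervals(25, g); mb <- random_intervals(25, g)
    mr <- random_intervals(80, g, max_w = 50)
    expect_equal(peak_intersect_fraction(mat_to_gr(ma), mat_to_gr(mb)),
                 oracle_peak_frac(ma, mb, g))
    expect_equal(bp_coverage_fraction(mat_to_gr(ma), mat_to_gr(mr)),
                 oracle_bp_frac(ma, mr, g))
    expect_equal(reads_per_100bp(mat_to_gr(ma), mat_to_gr(mr)),
                 oracle_reads_per_100bp(ma, mr))
  }
})

test_that("bp metrics are invariant to interval order and splitting", {
  set.seed(5)
  g <- 10000
  ma <- random_intervals(20, g); mr <- random_intervals(50, g)
  base <- bp_coverage_fraction(mat_to_gr(ma), mat_to_gr(mr))
  perm <- ma[sample(nrow(ma)), ]
  expect_equal(bp_coverage_fraction(mat_to_gr(perm), mat_to_gr(mr)), base)
  # split every peak into two adjacent pieces
  mid <- floor((ma[, 1] + ma[, 2]) / 2)
  keep <- mid > ma[, 1] & mid < ma[, 2]
  split <- rbind(cbind(ma[keep, 1], mid[keep]), cbind(mid[keep], ma[keep, 2]),
                 ma[!keep, , drop = FALSE])
  expect_equal(bp_coverage_fraction(mat_to_gr(split), mat_to_gr(mr)), base)
})

test_that("promoter windows extend -3 kb/+2 kb in reading direction with clipping", {
  tss <- data.frame(chrom = "chr1", pos = c(10000, 10000, 1000),
                    strand = c("+", "-", "+"))
  pw <- promoter_windows(tss)
  expect_equal(gr_to_mat(pw),
               rbind(c(7000, 12000), c(8000, 13000), c(0, 3000)),
               ignore_attr = TRUE)
  bad <- data.frame(chrom = "chr1", pos = 100, strand = ".")
  expect_error(promoter_windows(bad), "unknown strand")
  un <- promoter_windows(bad, allow_unstranded = TRUE)
  expect_equal(gr_to_mat(un), cbind(0, 2100), ignore_attr = TRUE)
})
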