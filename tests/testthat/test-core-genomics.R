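test_that("read_bed maps fields, keeps duplicates, and validates", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t200", f)
  x <- read_bed(f)
  expect_equal(nrow(x), 1L)
  expect_equal(x$chrom, "chr1")
  expect_equal(x$end - x$start, 200L)

  writeLines(character(), f)
  expect_equal(nrow(read_bed(f)), 0L)

  writeLines(c("chr1\t0\t100", "chr2\t50\t80", "chr1\t0\t100"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 3L)  # duplicates kept
  expect_equal(sum(x$chrom == "chr1" & x$start == 0L & x$end == 100L), 2L)

  writeLines(c("chr1\t0\t100", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\t0", f)
  expect_error(read_bed(f), "3 columns")
})

test_that("write_bed round-trips canonical 6-column BED byte-identically", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t200\ta\t0\t+", "chr2\t10\t30\tb\t5\t-"), f)
  g <- tempfile(fileext = ".bed")
  write_bed(read_bed(f), g)
  expect_identical(readLines(g), readLines(f))
})

test_that("read_chain enforces block arithmetic and parses spans", {
  ch <- make_chain(list(c(100, 0, 0)))[[1L]]
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$t_end - ch$t_start, 100)
  expect_equal(ch$q_end - ch$q_start, 100)

  # blocks (50, dt=10, dq=0), (40): target span 100, subject span 90
  ch <- make_chain(list(c(50, 10, 0), c(40, 0, 0)))[[1L]]
  expect_equal(ch$t_end - ch$t_start, 100)
  expect_equal(ch$q_end - ch$q_start, 90)
  expect_equal(ch$blocks$t_block_start, c(0, 60))

  # truncated / inconsistent chains are format errors
  f <- tempfile()
  writeLines(c("chain 1 chr1 100 + 0 100 chr1 100 + 0 90 1", "50 10 0", "41", ""), f)
  expect_error(read_chain(f), "arithmetic")
  writeLines(c("chain 1 chr1 100 + 0 100 chr1 100 + 0 100 1", "50 10 0"), f)
  expect_error(read_chain(f), "truncated|arithmetic")
})

test_that("negative-strand query coordinates normalize to forward strand", {
  # q on "-": printed q_start/q_end are reverse-strand; forward interval is
  # [q_size - q_end, q_size - q_start)
  ch <- make_chain(list(c(80, 0, 0)), q_strand = "-", q_start = 10,
                   q_size = 200)[[1L]]
  expect_equal(ch$q_fwd_start, 200 - 90)
  expect_equal(ch$q_fwd_end, 200 - 10)
})

test_that("read_repeatmasker converts .out coordinates and parses both dialects", {
  f <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin  end   (left)  repeat  class/family begin end (left) ID",
    "",
    " 1000  0.5 0.0 0.0 chr1 1 6000 (993999) + L1HS LINE/L1 1 6000 (0) 1",
    "  900  2.1 0.0 0.0 chr1 8000 8449 (991550) + LTR7 LTR/ERV1 1 450 (0) 2",
    "  800  1.0 0.0 0.0 chr2 10 6009 (993990) C L1HS LINE/L1 1 6000 (0) 3"), f)
  rm <- read_repeatmasker(f, "out")
  expect_equal(rm$start[1L], 0L)       # 1-based inclusive -> 0-based half-open
  expect_equal(rm$end[1L], 6000L)
  expect_equal(rm$strand[3L], "-")
  expect_equal(as.list(table(rm$repeat_name)), list(L1HS = 2L, LTR7 = 1L))
  expect_equal(rm$divergence_pct[2L], 2.1)
  expect_equal(rm$repeat_class, c("LINE", "LTR", "LINE"))

  b <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t550\tLTR7\tLTR\t+", b)
  rb <- read_repeatmasker(b, "bed")
  expect_equal(rb$repeat_name, "LTR7")
  expect_true(is.na(rb$divergence_pct))
})

test_that("interval intersection matches the all-pairs oracle and conventions", {
  one <- intersect_sets(data.table(chrom = "chr1", start = 0L, end = 200L),
                        data.table(chrom = "chr1", start = 100L, end = 300L))
  expect_equal(one$overlap_bp, 100L)
  # half-open abutment does not overlap
  expect_equal(nrow(intersect_sets(
    data.table(chrom = "chr1", start = 0L, end = 200L),
    data.table(chrom = "chr1", start = 200L, end = 300L))), 0L)

  set.seed(42)
  for (rep in 1:3) {
    a <- random_intervals(200L)
    b <- random_intervals(200L)
    for (mo in c(1L, 25L)) {
      got <- intersect_sets(a, b, mo)
      want <- brute_intersect(a, b, mo)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
    # symmetric up to pair order, independent of input ordering
    perm <- sample(nrow(a))
    got_perm <- intersect_sets(a[perm], b, 1L)
    got_perm[, idx_a := perm[idx_a]]
    expect_equal(as.data.frame(got_perm[order(idx_a, idx_b)]),
                 as.data.frame(intersect_sets(a, b, 1L)))
  }
})

test_that("window_around_midpoint follows the stated conventions", {
  w <- window_around_midpoint(1000L, 1001L, 200L)
  expect_equal(c(w$window_start, w$window_end), c(900L, 1100L))
  # left-clip preserves width by right shift
  w <- window_around_midpoint(0L, 1L, 200L)
  expect_equal(c(w$window_start, w$window_end), c(0L, 200L))
  # even-length peak: floor midpoint
  w <- window_around_midpoint(100L, 301L, 200L)
  expect_equal(w$midpoint, 200L)
  expect_equal(c(w$window_start, w$window_end), c(100L, 300L))
})

test_that("coverage and genome fraction use merged intervals", {
  x <- interval_set(data.table(chrom = "chr1",
                               start = c(0L, 50L, 200L, 0L),
                               end = c(100L, 150L, 300L, 100L)),
                    genome_size = c(chr1 = 1000))
  expect_equal(coverage_bp(x), 250)     # [0,150) + [200,300)
  expect_equal(genome_fraction(x), 0.25)
})
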