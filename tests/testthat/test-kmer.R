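test_that("mutant enumeration matches hand enumeration on tiny seeds", {
  seed <- seed_oligo("ACGC")
  expect_equal(seed$c_positions, c(2L, 4L))
  expect_equal(seed$labels, c("C1", "C2"))
  suppressWarnings({
    m1 <- enumerate_mutants(seed, min_len = 4L, max_len = 4L, order = 1L)
    m2 <- enumerate_mutants(seed, min_len = 4L, max_len = 4L, order = 2L)
  })
  expect_setequal(m1$sequence, c("ATGC", "ACGT"))
  expect_setequal(m2$sequence, c("ATGC", "ACGT", "ATGT"))
  expect_warning(enumerate_mutants(seed, min_len = 4L, max_len = 4L),
                 "min_len")
})

test_that("24-nt seed enumeration equals the brute-force oracle", {
  set.seed(8)
  seq24 <- paste(sample(c("A", "C", "G", "T"), 24, TRUE,
                        prob = c(0.2, 0.35, 0.2, 0.25)), collapse = "")
  seed <- seed_oligo(seq24)
  cat <- enumerate_mutants(seed, 12L, 24L, order = 1L)
  want <- brute_mutants(seq24, 12L, 24L)
  expect_setequal(cat$sequence, want)
  # every entry differs from the wild-type substring at exactly the
  # labelled positions (single-label entries only)
  single <- cat[!grepl("[;,]", labels)][seq_len(min(.N, 50L))]
  for (i in seq_len(nrow(single))) {
    w0 <- single$window_start[i]
    wt <- substr(seed$sequence, w0, w0 + single$length[i] - 1L)
    diffs <- which(strsplit(wt, "")[[1L]] != strsplit(single$sequence[i], "")[[1L]])
    lab_idx <- as.integer(sub("C", "", single$labels[i]))
    expect_equal(diffs, seed$c_positions[lab_idx] - w0 + 1L)
  }
})

test_that("genome scan counts exact loci like the sliding-window oracle", {
  set.seed(14)
  # planted query occurring a known number of times
  q <- "ACGTACGTTGCA"
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  genome <- paste0(filler(500), q, filler(300), q, filler(200), q, filler(100))
  got <- scan_genome(q, c(chr1 = genome), strands = "both")
  expect_equal(got$n_loci, brute_scan(q, genome))
  expect_gte(scan_genome(q, c(chr1 = genome), "forward")$n_loci, 3L)
  # palindromic query under both strands counted once per locus
  pal <- "ACGCGCGT"  # reverse complement of itself
  g2 <- paste0(filler(100), pal, filler(100))
  both <- scan_genome(pal, c(chr1 = g2), strands = "both")
  fwd <- scan_genome(pal, c(chr1 = g2), strands = "forward")
  expect_equal(both$n_loci, fwd$n_loci)
  expect_error(scan_genome("ACGN", c(chr1 = g2)), "non-ACGT")
})

test_that("random queries agree with the naive oracle on a sizeable fixture", {
  set.seed(16)
  genome <- paste(sample(c("A", "C", "G", "T"), 200000, TRUE), collapse = "")
  queries <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(8:12, 1L), TRUE), collapse = ""),
    "")
  got <- scan_genome(queries, c(chr1 = genome), strands = "both")
  for (i in seq_along(queries))
    expect_equal(got$n_loci[i], brute_scan(queries[i], genome))
})

test_that("scan invariants: strand symmetry and monotone append", {
  set.seed(18)
  genome <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  rc_genome <- chartr("ACGT", "TGCA",
                      paste(rev(strsplit(genome, "")[[1L]]), collapse = ""))
  queries <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""), "")
  suppressWarnings({
    a <- scan_genome(queries, c(chr1 = genome), strands = "both")
    b <- scan_genome(queries, c(chr1 = rc_genome), strands = "both")
    expect_equal(a$n_loci, b$n_loci)
    bigger <- scan_genome(queries, c(chr1 = paste0(genome, genome)), "both")
    expect_true(all(bigger$n_loci >= a$n_loci))
  })
})

test_that("per-position profile recovers planted asymmetry", {
  cat <- data.table(sequence = sprintf("SEQ%02d", 1:6),
                    length = 12L, labels = sprintf("C%d", 1:6),
                    window_start = 1L, mut_order = 1L, n_provenance = 1L)
  counts <- data.table(query = cat$sequence,
                       n_loci = c(1000L, 1100L, 900L, 100L, 90L, 110L))
  prof <- per_position_profile(cat, counts)
  expect_equal(prof$profile$label, sprintf("C%d", 1:6))
  expect_equal(prof$asymmetry_ratio, 1000 / 100)
  flat <- per_position_profile(cat, data.table(query = cat$sequence,
                                               n_loci = rep(50L, 6L)))
  expect_true(is.na(flat$asymmetry_ratio) || flat$asymmetry_ratio == 1)
  empty <- per_position_profile(hsreg:::empty_catalog(),
                                data.table(query = character(),
                                           n_loci = integer()))
  expect_equal(nrow(empty$profile), 0L)
})

test_that("cross-genome presence distinguishes primates from rodents", {
  co <- small_cohort()
  # the LTR7 consensus is present in human and primate genomes (planted
  # copies) but absent from rodents
  probe <- substr(co$genomes$consensus$LTR7, 10L, 29L)
  genomes <- lapply(co$genomes$genomes[c("human", "chimp", "gorilla",
                                         "mouse", "rat")], identity)
  pres <- cross_genome_presence(c(probe), genomes)
  expect_equal(unname(pres$matrix[1L, ]), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  none <- cross_genome_presence("ACGTACGTACGTACGTACGTACGTACGT", genomes)
  expect_equal(sum(none$matrix), 0L)
  expect_equal(none$fraction_in_all, 0)
})
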