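mk_calls <- function(pos, strand, chrom = "chr1", context = "CG") {
  data.table(chrom = chrom, pos = pos, strand = strand, context = context,
             kind = "hmC", level_pct = 30)
}

test_that("hmC proximity uses the half-window strict convention", {
  site <- data.table(tf = "NANOG", chrom = "chr1", midpoint = 1000L)
  inside <- hmc_proximity(site, mk_calls(1040L, "+"), windows_bp = 100L)
  expect_equal(inside$n_with_hmc, 1L)                   # +40 < 50
  outside <- hmc_proximity(site, mk_calls(1060L, "+"), windows_bp = 100L)
  expect_equal(outside$n_with_hmc, 0L)                  # +60 >= 50
  # narrower window can never beat the wider one
  set.seed(41)
  sites <- data.table(tf = "NANOG", chrom = "chr1",
                      midpoint = sample(100000L, 50L))
  calls <- mk_calls(sample(100000L, 200L),
                    sample(c("+", "-"), 200L, TRUE))
  hp <- hmc_proximity(sites, calls, windows_bp = c(100L, 1000L))
  expect_lte(hp[hp$window_bp == 100L, ]$fraction,
             hp[hp$window_bp == 1000L, ]$fraction)
})

test_that("planted adjacent-hmC fraction is recovered on the cohort", {
  cfg <- simulation_config(seed = 29, symbol_rate = 0, n_hmc_background = 0L)
  co <- simulate_cohort(cfg)
  hs <- co$features$sites[co$features$sites$truth_label == "human_specific" &
                            co$features$sites$tf == "NANOG", ]
  hp <- hmc_proximity(hs, co$features$methyl, windows_bp = c(100L, 1000L))
  n <- nrow(hs)
  for (w in c(100L, 1000L)) {
    rate <- if (w == 100L) cfg$hmc_rate_100bp else cfg$hmc_rate_1kb
    k <- hp[hp$window_bp == w, ]$n_with_hmc
    ci <- stats::binom.test(k, n)$conf.int
    expect_true(rate >= ci[1] && rate <= ci[2])
  }
})

test_that("symbol detection matches the exhaustive triple oracle", {
  one <- detect_symbols(mk_calls(c(10L, 20L, 30L), c("+", "-", "+")), 50L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$span_bp, 20L)
  none <- detect_symbols(mk_calls(c(10L, 20L, 30L), c("+", "+", "-")), 50L)
  expect_equal(nrow(none), 0L)
  # minus-strand flanks count too; span constraint enforced
  wide <- detect_symbols(mk_calls(c(10L, 40L, 70L), c("-", "+", "-")), 50L)
  expect_equal(nrow(wide), 0L)
  set.seed(43)
  calls <- mk_calls(sort(sample(100000L, 500L)),
                    sample(c("+", "-"), 500L, TRUE),
                    chrom = sample(c("chr1", "chr2"), 500L, TRUE))
  got <- detect_symbols(calls, 50L)
  want <- brute_symbols(calls, 50L)
  expect_equal(as.data.frame(got[order(chrom, p1), .(chrom, p1, p2, p3)]),
               as.data.frame(want))
})

test_that("symbol set is invariant under reverse-complementing the dataset", {
  set.seed(47)
  L <- 100000L
  calls <- mk_calls(sort(sample(L, 300L)), sample(c("+", "-"), 300L, TRUE))
  flipped <- copy(calls)[, pos := L - pos][, strand := ifelse(strand == "+", "-", "+")]
  a <- detect_symbols(calls, 50L)
  b <- detect_symbols(flipped, 50L)
  expect_equal(nrow(a), nrow(b))
  # each symbol maps to a flipped twin
  expect_setequal(L - a$p3, b$p1)
})

test_that("symbol colocalization uses the intersection rule", {
  site <- data.table(tf = "NANOG", chrom = "chr1", midpoint = 5000L)
  sym_in <- detect_symbols(mk_calls(c(5000L, 5010L, 5020L), c("+", "-", "+")), 50L)
  expect_equal(symbol_colocalization(site, sym_in, 1000L)$n_with_symbol, 1L)
  # straddling the window edge still counts
  sym_edge <- detect_symbols(mk_calls(c(5480L, 5495L, 5520L), c("+", "-", "+")), 50L)
  expect_equal(symbol_colocalization(site, sym_edge, 1000L)$n_with_symbol, 1L)
  sym_out <- detect_symbols(mk_calls(c(6000L, 6010L, 6020L), c("+", "-", "+")), 50L)
  expect_equal(symbol_colocalization(site, sym_out, 1000L)$n_with_symbol, 0L)
})

test_that("differential symbol colocalization between factors is detectable", {
  set.seed(53)
  n_a <- 60L; n_b <- 60L
  sites <- data.table(tf = rep(c("NANOG", "CTCF"), c(n_a, n_b)),
                      chrom = "chr1",
                      midpoint = seq(10000L, by = 5000L,
                                     length.out = n_a + n_b))
  # plant symbols near 40% of NANOG sites, none near CTCF
  planted <- sites[tf == "NANOG"][stats::runif(n_a) < 0.4]
  calls <- rbindlist(lapply(planted$midpoint, function(m)
    mk_calls(m + c(0L, 12L, 24L), c("+", "-", "+"))))
  sym <- detect_symbols(calls, 50L)
  col <- symbol_colocalization(sites, sym, 1000L)
  a <- col[col$tf == "NANOG", ]; b <- col[col$tf == "CTCF", ]
  ft <- fisher_2x2(matrix(c(a$n_with_symbol, a$n_sites - a$n_with_symbol,
                            b$n_with_symbol, b$n_sites - b$n_with_symbol),
                          2L, byrow = TRUE))
  expect_lt(ft$p_value, 0.01)
})
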