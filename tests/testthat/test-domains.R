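test_that("expected counts follow the random-placement identity", {
  sites <- data.table(chrom = "chr1", midpoint = seq(1000L, 167000L, by = 1000L))
  doms <- interval_set(data.table(chrom = "chr1", start = 0L, end = 429L))
  r <- place_in_domains(sites[1:167], doms, fraction = 0.429)
  expect_equal(r$expected_inside, 167 * 0.429)        # 71.64, printed as 72
  expect_equal(round(r$expected_inside), 72)
  # linear scaling in n and fraction
  r2 <- place_in_domains(sites[1:100], doms, fraction = 0.2)
  expect_equal(r2$expected_inside, 100 * 0.2)
  # fraction 1 -> expected = n and p = 1 when all inside
  all_in <- place_in_domains(data.table(chrom = "chr1", midpoint = c(10L, 20L)),
                             interval_set(data.table(chrom = "chr1", start = 0L,
                                                     end = 100L)),
                             fraction = 1)
  expect_equal(all_in$expected_inside, 2)
  expect_equal(all_in$p_binomial, 1)
})

test_that("random placement lands inside the binomial envelope across seeds", {
  doms <- interval_set(data.table(chrom = "chr1",
                                  start = seq(0L, 90000L, by = 10000L),
                                  end = seq(4000L, 94000L, by = 10000L)),
                       genome_size = c(chr1 = 100000))
  frac <- genome_fraction(doms)
  expect_equal(frac, 0.4)
  set.seed(31)
  inside <- vapply(1:20, function(i) {
    sites <- data.table(chrom = "chr1", midpoint = sample(0:99999, 200L))
    place_in_domains(sites, doms, fraction = frac)$n_inside
  }, 0L)
  # simultaneous envelope across the 20 draws (99.9% per draw)
  ci <- stats::qbinom(c(0.0005, 0.9995), 200L, frac)
  expect_true(all(inside >= ci[1] & inside <= ci[2]))
})

test_that("human-specific LAD derivation recovers planted truth", {
  # one chromosome, chain covering everything except a 6-kb human insertion
  chains <- make_chain(list(c(500000, 6000, 0), c(494000, 0, 0)))
  # 12 human LADs in fully-mapped territory clear of mouse LADs, 4 inside
  # mouse LADs, 1 overlapping the unmapped insertion
  hs_lads <- data.table(chrom = "chr1",
                        start = c(seq(10000L, 230000L, by = 20000L),
                                  seq(600000L, 660000L, by = 20000L),
                                  498000L),
                        end = c(seq(18000L, 238000L, by = 20000L),
                                seq(608000L, 668000L, by = 20000L),
                                510000L))
  stopifnot(nrow(hs_lads) == 17L)
  mouse_lad <- interval_set(data.table(chrom = "chr1", start = 590000L,
                                       end = 670000L))
  empty_mouse <- interval_set(data.table(chrom = "chr1", start = 900000L,
                                         end = 950000L))
  res <- derive_human_specific_lads(
    interval_set(hs_lads), chains,
    list(mouse_lad, empty_mouse, empty_mouse, empty_mouse))
  expect_equal(res$n_retained, 12L)
  expect_true(all(res$retained$start < 240000L))
  # output is a subset of the input and rerun-stable
  expect_true(all(res$retained$start %in% hs_lads$start))
  res2 <- derive_human_specific_lads(
    interval_set(hs_lads), chains,
    list(mouse_lad, empty_mouse, empty_mouse, empty_mouse))
  expect_identical(res$lads, res2$lads)
  # refusing to run without all four mouse sets
  expect_error(derive_human_specific_lads(interval_set(hs_lads), chains,
                                          list(mouse_lad)), "four")
})

test_that("domain length statistics reproduce fold ratios", {
  a <- interval_set(data.table(chrom = "chr1",
                               start = seq(0L, 9L) * 1000000L,
                               end = seq(0L, 9L) * 1000000L + 361000L))
  b <- interval_set(data.table(chrom = "chr1",
                               start = seq(0L, 9L) * 2000000L + 500000L,
                               end = seq(0L, 9L) * 2000000L + 1480000L))
  s <- domain_length_stats(a, b)
  expect_equal(s$mean_a, 361000)
  expect_equal(s$mean_b, 980000)
  expect_equal(s$ratio_disp, 2.7)                    # 980/361 = 2.71
  ident <- domain_length_stats(a, a)
  expect_equal(ident$ratio_disp, 1.0)
  expect_error(domain_length_stats(a, interval_set(
    data.table(chrom = character(), start = integer(), end = integer()))),
    "empty")
})

test_that("PMD colocalization recovers planted fractions", {
  co <- small_cohort()
  cl <- classify_sites(co$features$sites, co$chains$panel,
                       alt_chains = co$chains$alt_assembly)
  pm <- pmd_colocalization(cl, co$features$pmds)
  expect_true(all(pm$n_in_pmd <= pm$n))
  expect_true(all(pm$p_hypergeom >= 0 & pm$p_hypergeom <= 1))
  # planted-rate fixture: 90% of sites inside a PMD tiling
  set.seed(77)
  pmds <- interval_set(data.table(chrom = "chr1", start = 0L, end = 90000L))
  sites <- data.table(tf = "NANOG",
                      label = rep(c("human_specific", "shared"), c(50L, 50L)),
                      chrom = "chr1",
                      midpoint = c(sample(0:89999, 45L), sample(90000:99999, 5L),
                                   sample(0:99999, 50L)))
  got <- pmd_colocalization(sites, pmds)
  expect_equal(got[got$label == "human_specific", ]$n_in_pmd, 45L)
  expect_equal(got[got$label == "human_specific", ]$pct_in_pmd, 90)
})

test_that("midpoint rule agrees with >=50% window overlap for small windows", {
  co <- small_cohort()
  st <- co$features$sites
  doms <- co$features$lads
  mid_in <- hsreg:::midpoint_in_set(st, doms)
  ov <- intersect_sets(data.table(chrom = st$chrom, start = st$window_start,
                                  end = st$window_end),
                       as.data.table(doms)[, .(chrom, start, end)],
                       min_overlap_bp = co$config$window_bp / 2)
  ov_in <- seq_len(nrow(st)) %in% ov$idx_a
  expect_gte(mean(mid_in == ov_in), 0.95)  # disagreement only at domain edges
})
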