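test_that("thresholds are arithmetic means per gene class", {
  expect_equal(compute_threshold(c(10000, 30000))$threshold_bp, 20000)
  expect_equal(compute_threshold(5000)$threshold_bp, 5000)
  set.seed(13)
  d <- stats::rexp(100, rate = 1 / 25000)
  expect_equal(compute_threshold(d, "lncRNA")$threshold_bp, sum(d) / 100)
  expect_error(compute_threshold(numeric()), "empty")
})

test_that("proximal counting follows the strict-inequality distance rule", {
  genes <- data.table(gene_id = "g1", chrom = "chr1", start = 5000L, end = 7000L)
  # site inside the gene: distance 0, proximal for any positive threshold
  r <- count_proximal(data.table(chrom = "chr1", midpoint = 6000L), genes, 1)
  expect_equal(r$records$n_proximal_sites, 1L)
  # exactly at the threshold: excluded (strict <)
  r <- count_proximal(data.table(chrom = "chr1", midpoint = 4000L), genes, 1000)
  expect_equal(r$records$n_proximal_sites, 0L)
  r <- count_proximal(data.table(chrom = "chr1", midpoint = 4001L), genes, 1000)
  expect_equal(r$records$n_proximal_sites, 1L)
  # monotone in threshold
  set.seed(3)
  sites <- data.table(chrom = "chr1", midpoint = sample(100000L, 200L))
  genes <- data.table(gene_id = sprintf("g%d", 1:10), chrom = "chr1",
                      start = seq(0L, 90000L, by = 10000L),
                      end = seq(2000L, 92000L, by = 10000L))
  prev <- rep(0L, 10L)
  for (thr in c(500, 2000, 8000)) {
    cur <- count_proximal(sites, genes, thr)$records$n_proximal_sites
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("summary ratios reproduce published-table arithmetic", {
  # 24 genes on separate chromosomes; 20 carry 115 sites total, 4 carry none
  per_gene <- c(rep(6L, 15L), rep(5L, 5L), 0L, 0L, 0L, 0L)
  stopifnot(sum(per_gene) == 115L)
  genes <- data.table(gene_id = sprintf("g%02d", 1:24),
                      chrom = sprintf("c%02d", 1:24),
                      start = 10000L, end = 12000L)
  sites <- genes[rep(seq_len(24L), per_gene)][
    , .(chrom, midpoint = 11000L + seq_len(.N)), by = gene_id][, !"gene_id"]
  r <- count_proximal(sites, genes, 5000)
  expect_equal(r$summary$n_associated, 20L)
  expect_equal(round(r$summary$pct_associated), 83)        # 20/24
  expect_equal(r$summary$n_sites_associated, 115L)
  expect_equal(round(r$summary$sites_per_gene, 1), 5.8)    # 115/20
  # housekeeping analogue: 214 sites over 46 genes -> 4.7
  expect_equal(round(214 / 46, 1), 4.7)
})

test_that("rate correlation handles degenerate and exact cases", {
  rec <- data.table(ka_ks = c(0.1, 0.5, 0.9, 1.3),
                    n_proximal_sites = c(1L, 1L, 1L, 1L))
  r <- correlate_with_rate(rec, mode = "per_gene")
  expect_false(r$defined)                                 # zero variance
  rec2 <- data.table(ka_ks = seq(0.1, 1.5, by = 0.2),
                     n_proximal_sites = seq(2L, 16L, by = 2L))
  expect_equal(correlate_with_rate(rec2, mode = "per_gene")$r, 1.0)
  expect_equal(correlate_with_rate(rec2, mode = "rank_binned", bins = 4L)$r, 1.0)
})

test_that("planted positive slope is recovered by the binned correlation", {
  set.seed(19)
  rs <- replicate(50, {
    ka <- stats::runif(24, 0.05, 1.2)
    counts <- stats::rpois(24, lambda = 1 + 4 * ka)
    correlate_with_rate(data.table(ka_ks = ka, n_proximal_sites = counts))$r
  })
  expect_gt(mean(rs, na.rm = TRUE), 0.6)   # strong positive on average
})

test_that("window colocalization matches the all-pairs distance oracle", {
  feats <- data.table(chrom = "chr1", start = 100000L, end = 101000L)
  ev <- colocalize_window(data.table(site_id = "s1", chrom = "chr1",
                                     midpoint = 95000L), feats, 10000L)
  expect_equal(ev$n_events, 1L)                           # 5 kb away
  ev <- colocalize_window(data.table(site_id = "s1", chrom = "chr1",
                                     midpoint = 90000L), feats, 10000L)
  expect_equal(ev$n_events, 0L)                           # exactly 10 kb
  set.seed(23)
  sites <- data.table(site_id = sprintf("s%d", 1:40),
                      chrom = sample(c("chr1", "chr2"), 40, TRUE),
                      midpoint = sample(200000L, 40))
  feats <- random_intervals(30L, max_pos = 200000L, max_len = 2000L)
  got <- colocalize_window(sites, feats, 10000L)
  want <- 0L
  pairs <- list()
  for (i in 1:40) for (j in 1:30) {
    if (sites$chrom[i] != feats$chrom[j]) next
    d <- max(max(feats$start[j] - sites$midpoint[i],
                 sites$midpoint[i] - (feats$end[j] - 1L)), 0L)
    if (d < 10000L) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  expect_equal(got$n_events, length(pairs))
  if (length(pairs)) {
    want_dt <- data.table(idx_site = sapply(pairs, `[`, 1L),
                          idx_feature = sapply(pairs, `[`, 2L))
    expect_equal(got$events[, .(idx_site, idx_feature)],
                 want_dt[order(idx_site, idx_feature)])
    # pair count >= distinct sites and features involved
    expect_gte(got$n_events, got$n_sites)
    expect_gte(got$n_events, got$n_features)
  }
})
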