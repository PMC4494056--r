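#' Place sites in a domain set under the random-distribution model
#'
#' A site is inside a domain when its midpoint lies within a domain interval
#' (domains are >= 100 kb while windows are 200 bp, so the midpoint rule
#' matches per-site counting while staying deterministic at boundaries).
#' The expected inside count under random placement is
#' `n_sites * genome_fraction`; a two-sided binomial p-value is reported, and
#' a hypergeometric upper-tail p when a finite site universe is supplied.
#'
#' @param sites a `BindingSites`-like table (needs `chrom`, `midpoint`).
#' @param domains an `IntervalSet`.
#' @param genome_size named chromosome lengths (to derive the covered
#'   fraction) or `NULL` if `fraction` is given.
#' @param fraction covered genome fraction; overrides `genome_size`.
#' @param universe optional site universe (same columns as `sites`) for the
#'   hypergeometric test: successes = universe sites inside the domain set.
#' @return list of class `DomainPlacementResult`: `n_sites`, `n_inside`,
#'   `expected_inside`, `genome_fraction`, `p_binomial`, `p_hypergeom`,
#'   `inside` (per-site logical).
#' @export
place_in_domains <- function(sites, domains, genome_size = NULL,
                             fraction = NULL, universe = NULL) {
  dt <- as.data.table(sites)
  if (is.null(fraction)) {
    fraction <- genome_fraction(domains, genome_size)
  }
  if (fraction <= 0 || fraction > 1)
    stop("place_in_domains: fraction must be in (0, 1]")
  inside <- midpoint_in_set(dt, domains)
  n <- nrow(dt); k <- sum(inside)
  expected <- n * fraction
  # binom.test returns a logical p for p = 1; coerce
  p_binom <- if (n > 0) as.numeric(stats::binom.test(k, n, fraction)$p.value)
  else NA_real_
  p_hyper <- NA_real_
  if (!is.null(universe)) {
    u <- as.data.table(universe)
    K <- sum(midpoint_in_set(u, domains))
    p_hyper <- hypergeom_tail(k, n, K, nrow(u))
  }
  out <- list(n_sites = n, n_inside = k, expected_inside = expected,
              genome_fraction = fraction, p_binomial = p_binom,
              p_hypergeom = p_hyper, inside = inside)
  class(out) <- "DomainPlacementResult"
  out
}

## midpoint-inside-domain membership (vectorized, half-open domains)
midpoint_in_set <- function(sites, domains) {
  dm <- as.data.table(domains)
  pts <- data.table(chrom = sites$chrom, start = sites$midpoint,
                    end = sites$midpoint + 1L)
  hits <- intersect_sets(pts, dm[, .(chrom, start, end)], 1L)
  inside <- logical(nrow(sites))
  inside[unique(hits$idx_a)] <- TRUE
  inside
}

#' Derive human-specific lamina-associated domains
#'
#' A human LAD is retained when (1) it lifts to the mouse genome (best
#' single-chain block coverage >= `min_match`, the same rule the site
#' classifier uses) and (2) its mapped mouse span overlaps none of the four
#' mouse LAD sets (ESC, neural precursor, astrocyte, MEF) by more than
#' `overlap_tol_bp` (default 0: any overlap disqualifies).
#'
#' @param human_lads an `IntervalSet` of human LADs.
#' @param chains human-to-mouse `ChainSet`.
#' @param mouse_lad_sets list of exactly four `IntervalSet`s.
#' @param min_match minimum mapped fraction (default 0.95).
#' @param overlap_tol_bp mouse-LAD overlap tolerance in bp.
#' @return list of class `HumanSpecificLads`: `retained` (IntervalSet rows
#'   with mapped mouse span), `n_input`, `n_mapped`, `n_retained`,
#'   `mean_length_retained`, `mean_length_input`.
#' @export
derive_human_specific_lads <- function(human_lads, chains, mouse_lad_sets,
                                       min_match = 0.95, overlap_tol_bp = 0L) {
  if (length(mouse_lad_sets) != 4L)
    stop("derive_human_specific_lads: need all four mouse LAD sets")
  hl <- as.data.table(human_lads)
  n <- nrow(hl)
  mapped <- logical(n)
  q_chrom <- character(n); q_start <- integer(n); q_end <- integer(n)
  for (i in seq_len(n)) {
    best_cov <- 0; best <- NULL
    for (ch in chains) {
      if (!identical(ch$t_chrom, hl$chrom[i])) next
      b <- ch$blocks
      ov <- pmin(b$t_block_end, hl$end[i]) - pmax(b$t_block_start, hl$start[i])
      cov <- sum(pmax(ov, 0)) / (hl$end[i] - hl$start[i])
      if (cov > best_cov) { best_cov <- cov; best <- ch }
    }
    if (best_cov >= min_match) {
      mapped[i] <- TRUE
      sp <- map_span_to_query(best, hl$start[i], hl$end[i])
      q_chrom[i] <- best$q_chrom; q_start[i] <- sp[1L]; q_end[i] <- sp[2L]
    }
  }
  hl[, mapped := mapped]
  hl[, mouse_chrom := ifelse(mapped, q_chrom, NA_character_)]
  hl[, mouse_start := ifelse(mapped, q_start, NA_integer_)]
  hl[, mouse_end := ifelse(mapped, q_end, NA_integer_)]
  ok <- mapped
  verdicts <- matrix(NA, n, length(mouse_lad_sets))
  for (j in seq_along(mouse_lad_sets)) {
    ml <- as.data.table(mouse_lad_sets[[j]])
    for (i in which(mapped)) {
      sub <- ml[chrom == q_chrom[i]]
      ov <- if (nrow(sub))
        sum(pmax(pmin(sub$end, q_end[i]) - pmax(sub$start, q_start[i]), 0))
      else 0
      verdicts[i, j] <- ov <= overlap_tol_bp
      if (!verdicts[i, j]) ok[i] <- FALSE
    }
  }
  hl[, retained := ok]
  out <- list(lads = hl[],
              retained = hl[retained == TRUE],
              n_input = n, n_mapped = sum(mapped), n_retained = sum(ok),
              mean_length_retained = if (sum(ok)) mean(hl[retained == TRUE, end - start]) else NA_real_,
              mean_length_input = mean(hl$end - hl$start))
  class(out) <- "HumanSpecificLads"
  out
}

## map a target-side span through a chain to forward query coordinates,
## taking the query extent of the overlapping aligned blocks
map_span_to_query <- function(chain, t_start, t_end) {
  b <- chain$blocks
  q_block_start <- chain$q_start + cumsum(c(0, head(b$size + b$dq, -1L)))
  sel <- b$t_block_end > t_start & b$t_block_start < t_end
  if (!any(sel)) return(c(NA_integer_, NA_integer_))
  # clip terminal blocks to the span
  i1 <- which(sel)[1L]; i2 <- rev(which(sel))[1L]
  off1 <- max(0, t_start - b$t_block_start[i1])
  off2 <- max(0, b$t_block_end[i2] - t_end)
  qs <- q_block_start[i1] + off1
  qe <- q_block_start[i2] + b$size[i2] - off2
  if (identical(chain$q_strand, "-")) {
    c(as.integer(chain$q_size - qe), as.integer(chain$q_size - qs))
  } else c(as.integer(qs), as.integer(qe))
}

#' Length statistics for two domain sets
#'
#' Means, fold ratio of the second set's mean over the first's (to 1 dp in
#' the display field), and a two-sided test on the length distributions
#' (Mann-Whitney by default; Welch t available).
#'
#' @param domains_a,domains_b nonempty `IntervalSet`s.
#' @param test `"mann_whitney"` or `"welch"`.
#' @return list with `mean_a`, `mean_b`, `ratio` (unrounded), `ratio_disp`,
#'   `p_value`, `test`.
#' @export
domain_length_stats <- function(domains_a, domains_b,
                                test = c("mann_whitney", "welch")) {
  test <- match.arg(test)
  la <- interval_lengths(as.data.table(domains_a))
  lb <- interval_lengths(as.data.table(domains_b))
  if (!length(la) || !length(lb)) stop("domain_length_stats: empty set")
  p <- if (test == "mann_whitney")
    suppressWarnings(stats::wilcox.test(la, lb)$p.value)
  else stats::t.test(la, lb)$p.value
  ratio <- mean(lb) / mean(la)
  list(mean_a = mean(la), mean_b = mean(lb),
       ratio = ratio, ratio_disp = round(ratio, 1L),
       p_value = p, test = test)
}

#' Colocalization of classified sites with partially methylated domains
#'
#' For each TF and lineage label: the fraction of sites whose midpoint lies
#' inside a PMD, with an upper-tail hypergeometric p against the TF's full
#' site set as the universe.
#'
#' @param classified_sites a `SiteClassification` table.
#' @param pmds an `IntervalSet` of PMDs.
#' @return data.table with tf, label, n, n_in_pmd, pct_in_pmd, p_hypergeom.
#' @export
pmd_colocalization <- function(classified_sites, pmds) {
  dt <- as.data.table(classified_sites)
  dt[, .in_pmd := midpoint_in_set(dt, pmds)]
  on.exit(dt[, .in_pmd := NULL], add = TRUE)
  out <- dt[label != "unassessable", {
    uni <- dt[tf == .BY$tf & label != "unassessable"]
    N <- nrow(uni)
    K <- sum(uni$.in_pmd)
    k <- sum(.in_pmd)
    .(n = .N, n_in_pmd = k, pct_in_pmd = 100 * k / .N,
      p_hypergeom = hypergeom_tail(k, .N, K, N))
  }, by = .(tf, label)]
  out[]
}
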