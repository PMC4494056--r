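#' Proximity threshold from nearest-target distances
#'
#' The quantitative limit of proximity is the arithmetic mean of the
#' supplied nearest-target distances, computed separately per gene class
#' (protein-coding vs lncRNA targets have different characteristic
#' distances).
#'
#' @param distances nonnegative numeric vector of TF-to-nearest-target
#'   distances in bp.
#' @param gene_class label carried along (`"coding"` or `"lncRNA"`).
#' @return list of class `ProximityThreshold` with `gene_class`,
#'   `threshold_bp`, `n`.
#' @export
compute_threshold <- function(distances, gene_class = "coding") {
  if (!length(distances)) stop("compute_threshold: empty distance table")
  if (any(distances < 0)) stop("compute_threshold: negative distance")
  out <- list(gene_class = gene_class, threshold_bp = mean(distances),
              n = length(distances))
  class(out) <- "ProximityThreshold"
  out
}

## distance from a point to a [start, end) span; 0 inside
point_span_distance <- function(pos, start, end) {
  pmax(pmax(start - pos, pos - (end - 1L)), 0L)
}

#' Count binding sites proximal to genes
#'
#' A site is proximal to a gene when the distance from the site midpoint to
#' the gene span is strictly smaller than the threshold (0 when the midpoint
#' falls inside the gene). Each gene's count is tallied; the summary reports
#' associated genes (count >= 1), distinct associated sites, and the
#' sites-per-gene ratio (associated sites / associated genes).
#'
#' @param sites table with `chrom` and `midpoint` (e.g. the human-specific
#'   subset of a `SiteClassification`).
#' @param genes table with `gene_id`, `chrom`, `start`, `end` and optional
#'   `class`, `ka_ks`.
#' @param threshold a `ProximityThreshold` or a number (bp).
#' @return list of class `ProximityResult`: `records` (per gene:
#'   `n_proximal_sites`, `associated`) and `summary` (n_genes,
#'   n_associated, pct_associated, n_sites_associated, sites_per_gene).
#' @export
count_proximal <- function(sites, genes, threshold) {
  thr <- if (inherits(threshold, "ProximityThreshold")) threshold$threshold_bp
  else as.numeric(threshold)
  st <- as.data.table(sites)
  gn <- as.data.table(genes)
  counts <- integer(nrow(gn))
  site_hit <- logical(nrow(st))
  for (i in seq_len(nrow(gn))) {
    same <- st$chrom == gn$chrom[i]
    if (!any(same)) next
    d <- point_span_distance(st$midpoint[same], gn$start[i], gn$end[i])
    hit <- d < thr
    counts[i] <- sum(hit)
    site_hit[which(same)[hit]] <- TRUE
  }
  rec <- copy(gn)
  rec[, n_proximal_sites := counts]
  rec[, associated := counts >= 1L]
  n_assoc <- sum(rec$associated)
  summary <- list(
    n_genes = nrow(gn),
    n_associated = n_assoc,
    pct_associated = 100 * n_assoc / max(nrow(gn), 1L),
    n_sites_associated = sum(site_hit),
    sites_per_gene = if (n_assoc) sum(site_hit) / n_assoc else NA_real_)
  out <- list(records = rec[], summary = summary, threshold_bp = thr)
  class(out) <- "ProximityResult"
  out
}

#' Correlate per-gene proximal-site counts with evolutionary rate
#'
#' `per_gene` correlates Ka/Ks with the raw per-gene count. `rank_binned`
#' (the default, matching how small gene sets are usually summarized) sorts
#' genes by Ka/Ks, partitions them into `bins` groups of (near-)equal size,
#' and correlates bin-mean Ka/Ks with bin-mean count.
#'
#' @param records the `records` table from [count_proximal()] (needs
#'   `ka_ks`, `n_proximal_sites`).
#' @param mode `"rank_binned"` or `"per_gene"`.
#' @param bins number of rank bins (default 4).
#' @return list from [pearson_cor()] plus `mode`, `bins`.
#' @export
correlate_with_rate <- function(records, mode = c("rank_binned", "per_gene"),
                                bins = 4L) {
  mode <- match.arg(mode)
  dt <- as.data.table(records)[!is.na(ka_ks)]
  if (nrow(dt) < 3L) stop("correlate_with_rate: need >= 3 genes with ka_ks")
  if (mode == "per_gene") {
    res <- pearson_cor(dt$ka_ks, dt$n_proximal_sites)
  } else {
    dt <- dt[order(ka_ks)]
    dt[, .bin := cut(seq_len(.N), breaks = bins, labels = FALSE)]
    agg <- dt[, .(ka_ks = mean(ka_ks), count = mean(n_proximal_sites)),
              by = .bin]
    res <- pearson_cor(agg$ka_ks, agg$count)
  }
  c(res, list(mode = mode, bins = if (mode == "rank_binned") bins else NA))
}

#' Score 10-kb colocalization of sites with genomic features
#'
#' An event is a (site, feature) pair lying within the same continuous
#' window: the distance between the site midpoint and the feature span is
#' strictly less than `window_bp`. Reports all pairs, distinct sites and
#' features involved, and (when a site universe is supplied) an upper-tail
#' hypergeometric enrichment p with the universe's colocalized sites as
#' successes.
#'
#' @param sites table with `site_id`, `chrom`, `midpoint`.
#' @param features `IntervalSet`-like table (optional `name`).
#' @param window_bp window size (default 10,000).
#' @param universe optional full site set of the TF for enrichment.
#' @return list of class `ColocalizationResult`: `events` (pair table),
#'   `n_events`, `n_sites`, `n_features`, `p_hypergeom`.
#' @export
colocalize_window <- function(sites, features, window_bp = 10000L,
                              universe = NULL) {
  if (window_bp <= 0) stop("colocalize_window: window_bp must be positive")
  st <- as.data.table(sites)
  ft <- as.data.table(features)
  ev <- list()
  for (i in seq_len(nrow(ft))) {
    same <- which(st$chrom == ft$chrom[i])
    if (!length(same)) next
    d <- point_span_distance(st$midpoint[same], ft$start[i], ft$end[i])
    hit <- same[d < window_bp]
    if (length(hit))
      ev[[length(ev) + 1L]] <- data.table(idx_site = hit, idx_feature = i,
                                          distance_bp = d[d < window_bp])
  }
  events <- if (length(ev)) rbindlist(ev) else
    data.table(idx_site = integer(), idx_feature = integer(),
               distance_bp = integer())
  p_hyper <- NA_real_
  if (!is.null(universe)) {
    u <- as.data.table(universe)
    hit_u <- logical(nrow(u))
    for (i in seq_len(nrow(ft))) {
      same <- which(u$chrom == ft$chrom[i])
      if (!length(same)) next
      d <- point_span_distance(u$midpoint[same], ft$start[i], ft$end[i])
      hit_u[same[d < window_bp]] <- TRUE
    }
    p_hyper <- hypergeom_tail(length(unique(events$idx_site)), nrow(st),
                              sum(hit_u), nrow(u))
  }
  out <- list(events = events[order(idx_site, idx_feature)],
              n_events = nrow(events),
              n_sites = length(unique(events$idx_site)),
              n_features = length(unique(events$idx_feature)),
              p_hypergeom = p_hyper)
  class(out) <- "ColocalizationResult"
  out
}
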