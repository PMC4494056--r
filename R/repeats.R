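#' Annotate binding-site windows with repeat overlap
#'
#' A site is "within repeats" when its window overlaps at least one repeat
#' annotation by `min_overlap_bp` (default 1, the most permissive reading of
#' "intersected"). Each in-repeat site is assigned to the single repeat with
#' maximal overlap (ties broken by lower repeat start), so family counts sum
#' exactly to the number of in-repeat sites.
#'
#' @param sites a `BindingSites` or `SiteClassification` table.
#' @param repeats a `RepeatAnnotations` table.
#' @param min_overlap_bp minimum overlap in bp.
#' @return list of class `RepeatAssociationReport` with `per_site` (one row
#'   per site with its best-overlap repeat, `in_repeat` flag), `per_tf`
#'   (n_sites, n_in_repeats, pct_in_repeats, n_in_ltr_line, pct_in_ltr_line)
#'   and `pairs` (the raw site-repeat overlap pair table).
#' @export
annotate_repeat_overlap <- function(sites, repeats, min_overlap_bp = 1L) {
  dt <- as.data.table(sites)
  rp <- as.data.table(repeats)
  win <- dt[, .(chrom, start = window_start, end = window_end)]
  hits <- intersect_sets(win, rp[, .(chrom, start, end)], min_overlap_bp)
  per_site <- copy(dt)
  per_site[, in_repeat := FALSE]
  per_site[, best_repeat_name := NA_character_]
  per_site[, best_repeat_class := NA_character_]
  per_site[, best_overlap_bp := NA_integer_]
  if (nrow(hits)) {
    hits[, rep_start := rp$start[idx_b]]
    best <- hits[order(idx_a, -overlap_bp, rep_start), .SD[1L], by = idx_a]
    per_site[best$idx_a, `:=`(in_repeat = TRUE,
                              best_repeat_name = rp$repeat_name[best$idx_b],
                              best_repeat_class = rp$repeat_class[best$idx_b],
                              best_overlap_bp = best$overlap_bp)]
  }
  per_tf <- per_site[, {
    nin <- sum(in_repeat)
    nll <- sum(in_repeat & best_repeat_class %in% c("LINE", "LTR"))
    .(n_sites = .N, n_in_repeats = nin,
      pct_in_repeats = 100 * nin / max(.N, 1L),
      n_in_ltr_line = nll,
      pct_in_ltr_line = 100 * nll / max(.N, 1L))
  }, by = tf]
  out <- list(per_site = per_site[], per_tf = per_tf[],
              pairs = hits[, .(idx_site = idx_a, idx_repeat = idx_b,
                               chrom, overlap_bp)])
  class(out) <- "RepeatAssociationReport"
  out
}

#' Tabulate repeat family and class counts from a repeat-association report
#'
#' @param report a `RepeatAssociationReport`.
#' @return list with `families` (tf, repeat_name, n sites under unique
#'   assignment) and `classes` (tf, repeat_class, n).
#' @export
tabulate_families <- function(report) {
  ps <- report$per_site[in_repeat == TRUE]
  list(
    families = ps[, .(n = .N), by = .(tf, repeat_name = best_repeat_name)][
      order(tf, -n)],
    classes = ps[, .(n = .N), by = .(tf, repeat_class = best_repeat_class)][
      order(tf, -n)])
}

#' Classify L1 copies as full-length or truncated
#'
#' A copy is full-length when its genomic length falls inside `bounds`
#' (default 5,962-6,189 bp); an optional divergence ceiling restricts the
#' census to young copies. Non-L1 annotations are skipped with a message.
#'
#' @param repeats a `RepeatAnnotations` table.
#' @param bounds length bounds `c(lo, hi)` in bp, inclusive.
#' @param max_divergence_pct optional divergence filter (e.g. 1 for the
#'   "less than 1% divergence" census); `NULL` keeps all copies.
#' @return data.table with the L1 rows plus `length_bp` and
#'   `call` in {full_length, truncated}.
#' @export
classify_l1_completeness <- function(repeats, bounds = c(5962L, 6189L),
                                     max_divergence_pct = NULL) {
  rp <- as.data.table(repeats)
  is_l1 <- grepl("^L1", rp$repeat_name)
  if (any(!is_l1))
    message("classify_l1_completeness: skipping ", sum(!is_l1),
            " non-L1 annotation(s)")
  l1 <- rp[is_l1]
  if (!is.null(max_divergence_pct))
    l1 <- l1[!is.na(divergence_pct) & divergence_pct < max_divergence_pct]
  l1[, length_bp := end - start]
  l1[, call := ifelse(length_bp >= bounds[1L] & length_bp <= bounds[2L],
                      "full_length", "truncated")]
  l1[]
}
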