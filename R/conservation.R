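#' Score conservation of site sequences in individual genomes
#'
#' Presence in an individual is full-length sequence conservation: the
#' individual's sequence must cover the whole site window and match the
#' reference at `min_identity` or better (default 1.0, i.e. exact
#' full-length conservation). Cells with no retrievable sequence are
#' `uncallable` and excluded from denominators.
#'
#' @param sites a `BindingSites`-like table with `site_id`.
#' @param individuals named list, one entry per individual:
#'   `list(era = "modern"|"archaic", sequences = named character)` where
#'   `sequences[site_id]` is the individual's sequence over that window (NA
#'   or missing = uncallable), or `list(era =, calls = named logical)` for
#'   precomputed presence calls.
#' @param reference named character of reference window sequences per
#'   `site_id` (required when any individual supplies sequences).
#' @param min_identity minimum identity fraction.
#' @param full_length require full window coverage (length match).
#' @return list of class `ConservationMatrix`: `matrix` (character
#'   "present"/"absent"/"uncallable", sites x individuals), `era` (named
#'   vector per individual).
#' @export
score_conservation <- function(sites, individuals, reference = NULL,
                               min_identity = 1.0, full_length = TRUE) {
  st <- as.data.table(sites)
  ids <- st$site_id
  m <- matrix("uncallable", nrow = length(ids), ncol = length(individuals),
              dimnames = list(ids, names(individuals)))
  for (ind in names(individuals)) {
    spec <- individuals[[ind]]
    if (!is.null(spec$calls)) {
      calls <- spec$calls[ids]
      m[, ind] <- ifelse(is.na(calls), "uncallable",
                         ifelse(calls, "present", "absent"))
    } else if (!is.null(spec$sequences)) {
      if (is.null(reference))
        stop("score_conservation: reference sequences required")
      for (sid in ids) {
        s <- spec$sequences[[sid]]
        r <- reference[[sid]]
        if (is.null(s) || is.na(s) || is.null(r) || is.na(r)) next
        if (full_length && nchar(s) != nchar(r)) next
        n <- min(nchar(s), nchar(r))
        ident <- sum(strsplit(toupper(s), "")[[1L]][seq_len(n)] ==
                       strsplit(toupper(r), "")[[1L]][seq_len(n)]) / n
        m[sid, ind] <- if (ident >= min_identity) "present" else "absent"
      }
    } else stop("score_conservation: individual '", ind,
                "' has neither sequences nor calls")
  }
  era <- vapply(individuals, function(x) x$era, "")
  if (!all(era %in% c("modern", "archaic")))
    stop("score_conservation: era must be modern or archaic")
  out <- list(matrix = m, era = era)
  class(out) <- "ConservationMatrix"
  out
}

#' Cohort conservation summary
#'
#' Exact set algebra over the rows of a conservation matrix, restricted to
#' one era's columns: per-individual conserved percentage, the count and
#' percentage of sites conserved in all individuals, and the percentage
#' conserved in at least one. Sites uncallable in an individual are excluded
#' from that individual's denominator; the in-all/in-any statistics treat
#' uncallable cells as non-present and use the full site count as
#' denominator.
#'
#' @param cm a `ConservationMatrix`.
#' @param era which columns to summarize (default `"modern"`).
#' @return list with `per_individual` (data.table: individual, n_callable,
#'   n_present, pct), `n_sites`, `n_in_all`, `pct_in_all`, `pct_in_any`.
#' @export
cohort_summary <- function(cm, era = "modern") {
  cols <- names(cm$era)[cm$era == era]
  if (!length(cols)) stop("cohort_summary: no individuals with era ", era)
  m <- cm$matrix[, cols, drop = FALSE]
  per <- data.table(
    individual = cols,
    n_callable = colSums(m != "uncallable"),
    n_present = colSums(m == "present"))
  per[, pct := 100 * n_present / pmax(n_callable, 1L)]
  pres <- m == "present"
  n <- nrow(m)
  n_all <- sum(rowSums(pres) == ncol(m))
  n_any <- sum(rowSums(pres) >= 1L)
  list(per_individual = per[], n_sites = n,
       n_in_all = n_all, pct_in_all = 100 * n_all / n,
       n_in_any = n_any, pct_in_any = 100 * n_any / n)
}

#' Attribute site emergence relative to the archaic split
#'
#' A site is attributed to the post-split (modern-human) era when it is
#' absent in every archaic individual; sites present in at least one archaic
#' genome predate the split. Sites uncallable in all archaic individuals are
#' unassessable and excluded from the denominators; post-split and
#' archaic-present partition the assessable set.
#'
#' @param cm a `ConservationMatrix` with at least one archaic column.
#' @param split_years the population split time (default 370,000 years, the
#'   modern-human/Neanderthal estimate).
#' @return list with `n_assessable`, `n_post_split`, `n_archaic_present`,
#'   `fraction_post_split`, `fraction_archaic_present`, `split_years`,
#'   `per_site` (data.table: site_id, attribution).
#' @export
attribute_era <- function(cm, split_years = 370000) {
  cols <- names(cm$era)[cm$era == "archaic"]
  if (!length(cols)) stop("attribute_era: no archaic individuals")
  m <- cm$matrix[, cols, drop = FALSE]
  callable <- rowSums(m != "uncallable") >= 1L
  archaic_present <- rowSums(m == "present") >= 1L
  attribution <- ifelse(!callable, "unassessable",
                        ifelse(archaic_present, "pre_split", "post_split"))
  n_assess <- sum(callable)
  n_post <- sum(attribution == "post_split")
  n_arch <- sum(attribution == "pre_split")
  list(n_assessable = n_assess, n_post_split = n_post,
       n_archaic_present = n_arch,
       fraction_post_split = n_post / n_assess,
       fraction_archaic_present = n_arch / n_assess,
       split_years = split_years,
       per_site = data.table(site_id = rownames(m), attribution = attribution))
}
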