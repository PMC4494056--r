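#' Creation rate of novel binding sites per 100,000 years
#'
#' @param n_novel count of novel binding sites attributed to a lineage.
#' @param timeline_years evolutionary time over which they arose (> 0).
#' @return sites per 100,000 years (unrounded; display convention is 2 dp).
#' @export
rate_per_100k <- function(n_novel, timeline_years) {
  if (any(timeline_years <= 0)) stop("rate_per_100k: timeline must be positive")
  if (any(n_novel < 0)) stop("rate_per_100k: negative count")
  n_novel / (timeline_years / 1e5)
}

#' Years of evolution per novel binding site
#'
#' @param n_novel novel-site count (>= 1 for a defined value).
#' @param timeline_years evolutionary timeline.
#' @return years per site (unrounded; display convention is nearest
#'   integer); `NA` when `n_novel` is 0.
#' @export
years_per_site <- function(n_novel, timeline_years) {
  if (any(timeline_years <= 0)) stop("years_per_site: timeline must be positive")
  ifelse(n_novel >= 1, timeline_years / n_novel, NA_real_)
}

#' Fold acceleration of creation rates between two lineages
#'
#' Computed from unrounded rates (display convention 1 dp); the inverse
#' comparison is the exact reciprocal.
#'
#' @param n_num,t_num novel count and timeline of the numerator lineage.
#' @param n_den,t_den novel count and timeline of the denominator lineage.
#' @return fold ratio; `NA` when the denominator rate is 0.
#' @export
acceleration <- function(n_num, t_num, n_den, t_den) {
  r1 <- rate_per_100k(n_num, t_num)
  r2 <- rate_per_100k(n_den, t_den)
  ifelse(r2 > 0, r1 / r2, NA_real_)
}

#' Default lineage timelines (years)
#'
#' Mouse: ~350 Myr from the zebrafish/mouse split. Chimpanzee: ~75 Myr, the
#' Euarchonta/Glires split (~88 Ma) minus the human/chimp split (~13 Ma).
#' Modern humans: 370,000 years from the modern-human/Neanderthal split.
#'
#' @return named numeric vector.
#' @export
default_timelines <- function() {
  c(mouse = 350e6, chimpanzee = 75e6, modern_human = 370e3)
}

#' Published per-lineage novel-site inputs for the creation-rate model
#'
#' The printed input columns of the evolutionary model: per TF and lineage,
#' the novel-site count and its timeline. The mouse NANOG novel count is
#' derived as the mouse total minus the zebrafish total (16,667 - 14,010 =
#' 2,657); chimpanzee rows use the primate-specific counts; modern-human
#' rows use the human-specific counts under the stated assumption that all
#' human-specific sites emerged after the modern-human/Neanderthal split
#' (for NANOG, the archaic-conservation analysis refines this to the 794
#' post-split sites).
#'
#' @return data.table with `tf`, `lineage`, `n_novel`, `timeline_years`,
#'   `reference_lineage` (the lineage each acceleration is computed
#'   against).
#' @export
table_rate_inputs <- function() {
  tl <- default_timelines()
  data.table(
    tf = c("NANOG", "NANOG", "NANOG",
           "CTCF", "CTCF", "POU5F1", "POU5F1", "RNAPII", "RNAPII"),
    lineage = c("mouse", "chimpanzee", "modern_human",
                "chimpanzee", "modern_human",
                "chimpanzee", "modern_human",
                "chimpanzee", "modern_human"),
    n_novel = c(16667 - 14010, 28304, 794,
                28427, 591, 11617, 2386, 11693, 319),
    timeline_years = unname(tl[c("mouse", "chimpanzee", "modern_human",
                                 "chimpanzee", "modern_human",
                                 "chimpanzee", "modern_human",
                                 "chimpanzee", "modern_human")]),
    reference_lineage = c(NA, "mouse", "chimpanzee",
                          NA, "chimpanzee", NA, "chimpanzee",
                          NA, "chimpanzee"))
}

#' Build the full creation-rate table
#'
#' For every input row computes the rate per 100,000 years, years per site,
#' and the acceleration against the row's reference lineage (same TF).
#' The invariant `rate_per_100k * years_per_site = 100,000` is checked on
#' the unrounded values for every row.
#'
#' @param inputs data.table as returned by [table_rate_inputs()].
#' @return data.table of class `RateTable` with unrounded `rate_per_100k`,
#'   `years_per_site`, `acceleration`, plus display columns `rate_disp`
#'   (2 dp), `years_disp` (nearest integer), `accel_disp` (1 dp).
#' @export
build_rate_table <- function(inputs = table_rate_inputs()) {
  dt <- as.data.table(inputs)
  dt[, rate_per_100k := rate_per_100k(n_novel, timeline_years)]
  dt[, years_per_site := years_per_site(n_novel, timeline_years)]
  ok <- is.na(dt$years_per_site) |
    abs(dt$rate_per_100k * dt$years_per_site - 1e5) < 1e-6
  if (!all(ok))
    stop("build_rate_table: rate x years invariant violated in row(s) ",
         paste(which(!ok), collapse = ", "))
  accel <- rep(NA_real_, nrow(dt))
  for (i in seq_len(nrow(dt))) {
    ref <- dt$reference_lineage[i]
    if (is.na(ref)) next
    j <- which(dt$tf == dt$tf[i] & dt$lineage == ref)
    if (length(j) != 1L)
      stop("build_rate_table: reference lineage '", ref,
           "' not found for row ", i)
    accel[i] <- dt$rate_per_100k[i] / dt$rate_per_100k[j]
  }
  dt[, acceleration := accel]
  dt[, rate_disp := round(rate_per_100k, 2L)]
  dt[, years_disp := round(years_per_site)]
  dt[, accel_disp := round(acceleration, 1L)]
  setattr(dt, "class", c("RateTable", class(dt)))
  dt[]
}
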