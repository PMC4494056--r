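#' 5hmC proximity to binding sites
#'
#' A site is counted when at least one 5hmC call (either strand) lies within
#' half the window of the site midpoint (strictly: `|pos - midpoint| <
#' window_bp / 2`, so a call at midpoint + 60 is outside a 100-bp window).
#' Fractions at a narrower window can never exceed those at a wider one.
#'
#' @param sites a `BindingSites`-like table (per TF).
#' @param methyl_calls a `MethylCalls` table; rows with `kind != "hmC"` are
#'   dropped.
#' @param windows_bp numeric vector of window widths (default 100 and 1000).
#' @return data.table of class `HmcProximityResult`: tf, window_bp, n_sites,
#'   n_with_hmc, fraction.
#' @export
hmc_proximity <- function(sites, methyl_calls, windows_bp = c(100L, 1000L)) {
  st <- as.data.table(sites)
  mc <- as.data.table(methyl_calls)[kind == "hmC"]
  out <- rbindlist(lapply(windows_bp, function(w) {
    half <- w / 2
    hit <- logical(nrow(st))
    for (cc in unique(st$chrom)) {
      pos <- mc[chrom == cc, pos]
      idx <- which(st$chrom == cc)
      if (!length(pos) || !length(idx)) next
      for (i in idx)
        hit[i] <- any(abs(pos - st$midpoint[i]) < half)
    }
    st[, .(window_bp = w, n_sites = .N, n_with_hmc = sum(hit[.I]),
           fraction = sum(hit[.I]) / .N), by = tf]
  }))
  setattr(out, "class", c("HmcProximityResult", class(out)))
  out[]
}

#' Compare 5hmC proximity fractions between two factors
#'
#' Two-sided Fisher 2x2 on (with hmC, without) counts of two TFs at one
#' window width.
#'
#' @param result an `HmcProximityResult`.
#' @param tf_a,tf_b factor names.
#' @param window which window width to compare.
#' @return [fisher_2x2()] result.
#' @export
hmc_proximity_test <- function(result, tf_a, tf_b, window) {
  r <- as.data.table(result)
  a <- r[r$tf == tf_a & r$window_bp == window, ]
  b <- r[r$tf == tf_b & r$window_bp == window, ]
  if (nrow(a) != 1L || nrow(b) != 1L) stop("hmc_proximity_test: missing row")
  fisher_2x2(matrix(c(a$n_with_hmc, a$n_sites - a$n_with_hmc,
                      b$n_with_hmc, b$n_sites - b$n_with_hmc), 2L, byrow = TRUE))
}

#' Detect the strand-asymmetric three-letter 5hmC symbol
#'
#' Scans consecutive triples of hmC calls (CG context, sorted by position
#' within each chromosome). A triple `(p1 < p2 < p3)` is a symbol when the
#' middle call sits on the opposite strand from the two flanks (`s1 == s3`,
#' `s2 != s1`) and the span `p3 - p1` does not exceed `max_span`.
#' Overlapping symbols are allowed.
#'
#' @param methyl_calls a `MethylCalls` table.
#' @param max_span maximum symbol span in bp (default 50).
#' @return data.table of class `HmcSymbols`: chrom, p1, p2, p3, s1, s2, s3,
#'   span_bp.
#' @export
detect_symbols <- function(methyl_calls, max_span = 50L) {
  mc <- as.data.table(methyl_calls)[kind == "hmC" & context == "CG"]
  out <- mc[order(chrom, pos), {
    n <- .N
    if (n < 3L) NULL else {
      i <- seq_len(n - 2L)
      keep <- strand[i] == strand[i + 2L] & strand[i + 1L] != strand[i] &
        (pos[i + 2L] - pos[i]) <= max_span
      if (!any(keep)) NULL else {
        i <- i[keep]
        .(p1 = pos[i], p2 = pos[i + 1L], p3 = pos[i + 2L],
          s1 = strand[i], s2 = strand[i + 1L], s3 = strand[i + 2L],
          span_bp = pos[i + 2L] - pos[i])
      }
    }
  }, by = chrom]
  if (!nrow(out))
    out <- data.table(chrom = character(), p1 = integer(), p2 = integer(),
                      p3 = integer(), s1 = character(), s2 = character(),
                      s3 = character(), span_bp = integer())
  setattr(out, "class", c("HmcSymbols", class(out)))
  out[]
}

#' Colocalization of three-letter 5hmC symbols with binding sites
#'
#' A site is counted when at least one symbol's span `[p1, p3]` intersects
#' the window of width `window_bp` centered at the site midpoint (a symbol
#' straddling the window edge counts).
#'
#' @param sites a `BindingSites`-like table.
#' @param symbols an `HmcSymbols` table.
#' @param window_bp window width (default 1000).
#' @return data.table per TF: n_sites, n_with_symbol, fraction.
#' @export
symbol_colocalization <- function(sites, symbols, window_bp = 1000L) {
  st <- as.data.table(sites)
  sy <- as.data.table(symbols)
  half <- as.integer(window_bp / 2)
  hit <- logical(nrow(st))
  for (cc in unique(st$chrom)) {
    s <- sy[chrom == cc]
    idx <- which(st$chrom == cc)
    if (!nrow(s) || !length(idx)) next
    for (i in idx) {
      w0 <- st$midpoint[i] - half; w1 <- st$midpoint[i] + half
      hit[i] <- any(s$p3 >= w0 & s$p1 < w1)
    }
  }
  st[, .(n_sites = .N, n_with_symbol = sum(hit[.I]),
         fraction = sum(hit[.I]) / .N), by = tf]
}
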