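#' Upper-tail hypergeometric test
#'
#' Probability of drawing at least `k` successes in `n` draws without
#' replacement from a universe of `N` containing `K` successes. Computed on
#' the log-safe upper-tail parameterization of [stats::phyper()], stable for
#' universes up to at least 1e7.
#'
#' @param k successes drawn.
#' @param n draws.
#' @param K successes in the universe.
#' @param N universe size.
#' @return `P(X >= k)`.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) + 0 || n > N || K > N)
    stop("hypergeom_tail: inconsistent counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of probabilities of all tables (with the
#' observed margins) whose hypergeometric probability does not exceed the
#' observed table's, computed directly by enumeration over [stats::dhyper()].
#' The odds ratio is the sample odds ratio; when any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and flagged.
#'
#' @param tab 2x2 matrix (or 4-vector a,b,c,d row-wise) of nonnegative counts.
#' @return list with `p_value`, `odds_ratio`, `haldane_corrected`.
#' @export
fisher_2x2 <- function(tab) {
  m <- matrix(as.numeric(tab), 2L, 2L, byrow = is.null(dim(tab)))
  if (any(m < 0) || any(m != round(m))) stop("fisher_2x2: cells must be nonnegative integers")
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  K <- a + b          # row-1 margin
  N <- a + b + c + d
  n <- a + c          # column-1 margin
  if (N == 0) stop("fisher_2x2: all-zero table")
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  xs <- lo:hi
  probs <- stats::dhyper(xs, K, N - K, n)
  p_obs <- stats::dhyper(a, K, N - K, n)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  corrected <- any(m == 0)
  if (corrected) m <- m + 0.5
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(p_value = p, odds_ratio = or, haldane_corrected = corrected)
}

#' Pearson correlation with two-sided significance
#'
#' r by the standard product-moment formula; p from the t distribution with
#' n - 2 degrees of freedom. Zero variance in either vector yields an
#' undefined (NA) r, flagged rather than erroring.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p_value`, `n`, `defined`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_cor: length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("pearson_cor: need >= 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p_value = p, n = n, defined = TRUE)
}

#' Event density per consecutive chromosome bin
#'
#' Counts events in left-closed bins `[i*b, (i+1)*b)`; the number of bins is
#' `ceiling(chrom_length / bin_size)` and bin counts conserve the total
#' event count.
#'
#' @param events data.frame with `chrom` and `pos` (0-based positions).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size bin width in bp (1e6 and 1e3 are the conventional scales).
#' @return data.table of class `DensityProfile`: `chrom`, `bin` (0-based),
#'   `bin_start`, `count`.
#' @export
density_profile <- function(events, chrom_sizes, bin_size = 1e6) {
  ev <- as.data.table(events)
  if (nrow(ev)) {
    len <- chrom_sizes[ev$chrom]
    if (anyNA(len)) stop("density_profile: event on unknown chromosome")
    if (any(ev$pos >= len | ev$pos < 0))
      stop("density_profile: event beyond chromosome size")
  }
  out <- rbindlist(lapply(names(chrom_sizes), function(cc) {
    nb <- as.integer(ceiling(chrom_sizes[[cc]] / bin_size))
    cnt <- tabulate(ev[chrom == cc, floor(pos / bin_size)] + 1L, nbins = nb)
    data.table(chrom = cc, bin = seq_len(nb) - 1L,
               bin_start = (seq_len(nb) - 1L) * bin_size, count = cnt)
  }))
  setattr(out, "class", c("DensityProfile", class(out)))
  out[]
}

#' Correlate two density profiles
#'
#' `mode = "bins"` correlates the concatenated per-chromosome bin vectors;
#' `mode = "per_chrom"` correlates per-chromosome event totals (one point per
#' chromosome), the default the chromosomal-distribution comparisons use.
#'
#' @param a,b `DensityProfile` objects over the same chromosomes/binning.
#' @param mode `"per_chrom"` or `"bins"`.
#' @return list with `r`, `p_value`, `n`, `defined` (see [pearson_cor()]).
#' @export
profile_correlation <- function(a, b, mode = c("per_chrom", "bins")) {
  mode <- match.arg(mode)
  a <- as.data.table(a); b <- as.data.table(b)
  if (mode == "bins") {
    m <- merge(a, b, by = c("chrom", "bin"), suffixes = c("_a", "_b"))
    pearson_cor(m$count_a, m$count_b)
  } else {
    ta <- a[, .(count = sum(count)), by = chrom]
    tb <- b[, .(count = sum(count)), by = chrom]
    m <- merge(ta, tb, by = "chrom", suffixes = c("_a", "_b"))
    pearson_cor(m$count_a, m$count_b)
  }
}
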