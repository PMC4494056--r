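#' @import data.table
#' @importFrom stats setNames
NULL

## All internal coordinates are 0-based half-open (BED convention).
## 1-based inputs (RepeatMasker .out) are converted on read.

#' Construct an interval set
#'
#' The basic container for genomic intervals: a `data.table` with columns
#' `chrom`, `start`, `end` (0-based half-open) and optional `name`, `score`
#' and `strand`, carrying an optional per-chromosome genome size. Duplicated
#' intervals are retained (binding "events" are counted per event); coverage
#' computations use a merged copy internally.
#'
#' @param x data.frame with at least `chrom`, `start`, `end`.
#' @param genome_size optional named numeric vector of chromosome lengths (bp).
#' @return An object of class `IntervalSet` (a `data.table`).
#' @export
interval_set <- function(x, genome_size = NULL) {
  dt <- as.data.table(x)
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("interval_set: missing columns: ", paste(missing_cols, collapse = ", "))
  dt[, chrom := as.character(chrom)]
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  if (nrow(dt)) {
    if (any(dt$start < 0)) stop("interval_set: negative start coordinate")
    if (any(dt$end <= dt$start)) stop("interval_set: end <= start")
  }
  if (!is.null(genome_size)) {
    if (is.null(names(genome_size)))
      stop("interval_set: genome_size must be a named vector")
    setattr(dt, "genome_size", genome_size)
  }
  setattr(dt, "class", c("IntervalSet", class(dt)))
  dt
}

#' @export
print.IntervalSet <- function(x, ...) {
  cat(sprintf("IntervalSet: %d intervals on %d chromosome(s)\n",
              nrow(x), data.table::uniqueN(x$chrom)))
  NextMethod()
}

#' Interval lengths
#' @param x an `IntervalSet`.
#' @return integer vector of `end - start`.
#' @export
interval_lengths <- function(x) x$end - x$start

#' Merge overlapping/abutting intervals (per chromosome)
#'
#' Used for coverage computations; the original (possibly duplicated) events
#' are never collapsed elsewhere.
#'
#' @param x an `IntervalSet`.
#' @return an `IntervalSet` of disjoint intervals.
#' @export
merge_intervals <- function(x) {
  if (!nrow(x)) return(interval_set(x))
  pieces <- lapply(split(x, x$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.table(chrom = d$chrom[1L],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  out <- rbindlist(pieces)
  interval_set(out[order(chrom, start)],
               genome_size = attr(x, "genome_size", exact = TRUE))
}

#' Total covered bases
#'
#' @param x an `IntervalSet`.
#' @param chrom optional single chromosome to restrict to.
#' @return total merged coverage in bp.
#' @export
coverage_bp <- function(x, chrom = NULL) {
  m <- merge_intervals(x)
  if (!is.null(chrom)) m <- m[m$chrom == chrom, ]
  sum(as.numeric(m$end - m$start))
}

#' Fraction of the genome covered by an interval set
#'
#' @param x an `IntervalSet` whose `genome_size` attribute is set, or
#'   supply `genome_size` explicitly.
#' @param genome_size optional named vector of chromosome lengths.
#' @return covered fraction in `[0, 1]`.
#' @export
genome_fraction <- function(x, genome_size = NULL) {
  gs <- if (is.null(genome_size)) attr(x, "genome_size", exact = TRUE) else genome_size
  if (is.null(gs)) stop("genome_fraction: genome_size unknown")
  coverage_bp(x) / sum(as.numeric(gs))
}

#' Read a BED file
#'
#' BED 0-based half-open coordinates are preserved; optional name, score and
#' strand columns are retained. Duplicate intervals are kept. Input line
#' order does not affect downstream results.
#'
#' @param path file path.
#' @param one_based if `TRUE`, input starts are 1-based inclusive and are
#'   shifted to the internal 0-based convention.
#' @param genome_size optional named vector of chromosome lengths.
#' @return an `IntervalSet`.
#' @export
read_bed <- function(path, one_based = FALSE, genome_size = NULL) {
  if (!file.exists(path)) stop("read_bed: no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx))
    return(interval_set(data.table(chrom = character(), start = integer(),
                                   end = integer()), genome_size = genome_size))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("read_bed: line ", idx[which(nf < 3L)[1L]], ": fewer than 3 columns")
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad))
    stop("read_bed: line ", idx[bad[1L]], ": non-numeric coordinates")
  if (one_based) starts <- starts - 1L
  bad <- which(ends <= starts)
  if (length(bad))
    stop("read_bed: line ", idx[bad[1L]], ": end <= start")
  dt <- data.table(chrom = vapply(fields, `[`, "", 1L),
                   start = starts, end = ends)
  if (any(nf >= 4L)) dt[, name := vapply(fields, function(f)
    if (length(f) >= 4L) f[4L] else NA_character_, "")]
  if (any(nf >= 5L)) dt[, score := vapply(fields, function(f)
    if (length(f) >= 5L) f[5L] else NA_character_, "")]
  if (any(nf >= 6L)) dt[, strand := vapply(fields, function(f)
    if (length(f) >= 6L) f[6L] else ".", "")]
  interval_set(dt, genome_size = genome_size)
}

#' Write a BED file
#'
#' Emits 3 to 6 columns depending on which optional columns are present;
#' round-trips canonical 6-column BED byte-identically.
#'
#' @param x an `IntervalSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  for (opt in c("name", "score", "strand"))
    if (opt %in% names(x)) cols <- c(cols, opt) else break
  dt <- as.data.table(x)[, cols, with = FALSE]
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Intersect two interval sets
#'
#' Returns every pair of intervals (one from `a`, one from `b`) on the same
#' chromosome whose overlap is at least `min_overlap_bp`. Output is
#' independent of input ordering; half-open abutting intervals do not
#' overlap.
#'
#' @param a,b `IntervalSet` objects (or data.frames with chrom/start/end).
#' @param min_overlap_bp minimum overlap in bp (>= 1).
#' @return data.table with `idx_a`, `idx_b` (row indices into the inputs),
#'   `chrom` and `overlap_bp`.
#' @export
intersect_sets <- function(a, b, min_overlap_bp = 1L) {
  if (min_overlap_bp < 1L) stop("intersect_sets: min_overlap_bp must be >= 1")
  a <- as.data.table(a); b <- as.data.table(b)
  empty <- data.table(idx_a = integer(), idx_b = integer(),
                      chrom = character(), overlap_bp = integer())
  if (!nrow(a) || !nrow(b)) return(empty)
  a[, .row_a := .I]; b[, .row_b := .I]
  on.exit({a[, .row_a := NULL]; b[, .row_b := NULL]}, add = TRUE)
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (!length(chroms)) return(empty)
  out <- lapply(chroms, function(cc) {
    da <- a[chrom == cc]; db <- b[chrom == cc]
    ira <- IRanges::IRanges(da$start + 1L, da$end)
    irb <- IRanges::IRanges(db$start + 1L, db$end)
    hits <- IRanges::findOverlaps(ira, irb, minoverlap = min_overlap_bp)
    if (!length(hits)) return(NULL)
    qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
    ov <- pmin(da$end[qa], db$end[qb]) - pmax(da$start[qa], db$start[qb])
    data.table(idx_a = da$.row_a[qa], idx_b = db$.row_b[qb],
               chrom = cc, overlap_bp = as.integer(ov))
  })
  out <- rbindlist(out)
  if (!nrow(out)) return(empty)
  out[order(idx_a, idx_b)]
}

#' Fixed-width window centered on a peak midpoint
#'
#' The midpoint of a peak `[start, end)` is `floor((start + end) / 2)`
#' (left-of-center for even-length peaks). The window is
#' `[mid - floor(w/2), mid + ceiling(w/2))`; windows clipped at position 0
#' are right-shifted so that the width is preserved.
#'
#' @param start,end integer vectors of peak coordinates (0-based half-open).
#' @param width window width in bp (default 200).
#' @return data.table with `midpoint`, `window_start`, `window_end`.
#' @export
window_around_midpoint <- function(start, end, width = 200L) {
  if (width < 1L) stop("window_around_midpoint: width must be >= 1")
  mid <- as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
  w0 <- mid - as.integer(floor(width / 2))
  w1 <- mid + as.integer(ceiling(width / 2))
  shift <- pmax(0L, -w0)
  data.table(midpoint = mid, window_start = w0 + shift, window_end = w1 + shift)
}

#' Build binding sites from peaks
#'
#' Attaches the factor name, the peak midpoint and a fixed-width window to
#' each peak interval. Sites whose window would run past the end of a known
#' chromosome are flagged unassessable rather than dropped.
#'
#' @param peaks an `IntervalSet` of ChIP peaks.
#' @param tf factor name (recycled) or per-peak character vector.
#' @param width window width (default 200 bp).
#' @param genome_size optional named chromosome lengths used to flag windows
#'   that do not fit.
#' @return data.table with class `BindingSites`: `site_id`, `tf`, `chrom`,
#'   peak `start`/`end`, `midpoint`, `window_start`, `window_end`,
#'   `assessable`.
#' @export
binding_sites <- function(peaks, tf, width = 200L, genome_size = NULL) {
  dt <- as.data.table(peaks)[, .(chrom, start, end)]
  dt[, tf := tf]
  win <- window_around_midpoint(dt$start, dt$end, width)
  dt <- cbind(dt, win)
  dt[, site_id := sprintf("%s_%06d", tf, seq_len(.N)), by = tf]
  if (is.null(genome_size))
    gs <- attr(peaks, "genome_size", exact = TRUE)
  else gs <- genome_size
  dt[, assessable := TRUE]
  if (!is.null(gs)) {
    len <- gs[dt$chrom]
    dt[!is.na(len) & window_end > len, assessable := FALSE]
  }
  setcolorder(dt, c("site_id", "tf", "chrom", "start", "end",
                    "midpoint", "window_start", "window_end", "assessable"))
  setattr(dt, "class", c("BindingSites", class(dt)))
  dt[]
}
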