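#' Read repeat annotations
#'
#' Supports the standard RepeatMasker `.out` dialect (15-column body after a
#' 3-line header; 1-based inclusive coordinates, converted to the internal
#' 0-based half-open convention) and a BED dialect where the name column is
#' `repeat_name` and an optional 7th column is `repeat_class` (divergence is
#' then unavailable).
#'
#' @param path file path.
#' @param dialect `"out"` or `"bed"`.
#' @return data.table of class `RepeatAnnotations` with `chrom`, `start`,
#'   `end`, `strand`, `repeat_name`, `repeat_class`, `divergence_pct`, and
#'   consensus span columns `cons_begin`, `cons_end`, `cons_left` (NA in the
#'   BED dialect).
#' @export
read_repeatmasker <- function(path, dialect = c("out", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_repeatmasker: no such file: ", path)
  if (dialect == "bed") {
    bed <- read_bed(path)
    dt <- as.data.table(bed)
    dt[, repeat_name := if ("name" %in% names(dt)) name else NA_character_]
    dt[, repeat_class := if ("score" %in% names(dt)) score else NA_character_]
    if (!"strand" %in% names(dt)) dt[, strand := "."]
    out <- dt[, .(chrom, start, end, strand, repeat_name, repeat_class,
                  divergence_pct = NA_real_, cons_begin = NA_integer_,
                  cons_end = NA_integer_, cons_left = NA_integer_)]
  } else {
    lines <- readLines(path)
    # 3 header lines (column banner + blank); tolerate files without them
    body <- lines[!grepl("^\\s*$", lines)]
    if (length(body) && grepl("^\\s*SW", body[1L])) body <- body[-(1:2)]
    if (!length(body))
      out <- data.table(chrom = character(), start = integer(), end = integer(),
                        strand = character(), repeat_name = character(),
                        repeat_class = character(), divergence_pct = numeric(),
                        cons_begin = integer(), cons_end = integer(),
                        cons_left = integer())
    else {
      f <- strsplit(trimws(body), "\\s+")
      nf <- lengths(f)
      if (any(nf < 15L))
        stop("read_repeatmasker: malformed .out row (", min(nf), " fields)")
      g <- function(i) vapply(f, `[`, "", i)
      strip <- function(v) as.integer(gsub("[()]", "", v))
      out <- data.table(
        chrom = g(5L),
        start = as.integer(g(6L)) - 1L,  # 1-based inclusive -> 0-based half-open
        end = as.integer(g(7L)),
        strand = ifelse(g(9L) == "C", "-", "+"),
        repeat_name = g(10L),
        repeat_class = sub("/.*$", "", g(11L)),
        divergence_pct = as.numeric(g(2L)),
        cons_begin = strip(g(12L)),
        cons_end = strip(g(13L)),
        cons_left = strip(g(14L)))
    }
  }
  if (nrow(out) && any(out$divergence_pct < 0, na.rm = TRUE))
    stop("read_repeatmasker: negative divergence")
  setattr(out, "class", c("RepeatAnnotations", class(out)))
  out[]
}

#' Write repeat annotations in the package's tab-delimited form
#' @param x a `RepeatAnnotations` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(x, path) {
  write_tsv(as.data.table(x), path)
}

#' Read a base-resolution methylation/5hmC table
#'
#' Tab-delimited with a single commented header line:
#' `chrom pos strand context kind level_pct`; `pos` is the 0-based offset of
#' the cytosine, `context` one of CG/CHG/CHH, `kind` one of mC/hmC.
#'
#' @param path file path.
#' @return data.table of class `MethylCalls`.
#' @export
read_methyl <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  setnames(dt, sub("^#\\s*", "", names(dt)))
  need <- c("chrom", "pos", "strand", "context", "kind", "level_pct")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("read_methyl: missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(dt) && !all(dt$strand %in% c("+", "-")))
    stop("read_methyl: strand must be + or -")
  if (nrow(dt) && !all(dt$context %in% c("CG", "CHG", "CHH")))
    stop("read_methyl: bad context value")
  setattr(dt, "class", c("MethylCalls", class(dt)))
  dt[]
}

#' Write a methylation table
#' @param x a `MethylCalls` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methyl <- function(x, path) {
  write_tsv(as.data.table(x), path)
}

## shared writer: tab-delimited UTF-8, single commented header line
write_tsv <- function(dt, path) {
  header <- paste0("#", paste(names(dt), collapse = "\t"))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(header, con)
  close(con)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE, append = TRUE)
  invisible(path)
}

#' Read a table written by the package's writers
#' @param path file path.
#' @return data.table.
#' @export
read_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  dt <- fread(path, sep = "\t", header = FALSE, skip = 1L)
  if (nrow(dt) == 0L) {
    dt <- fread(text = paste0(sub("^#", "", first), "\n"), sep = "\t")
    return(dt[0L])
  }
  setnames(dt, strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1L]])
  dt[]
}
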