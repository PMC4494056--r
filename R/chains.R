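## UCSC chain format: header
##   chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id
## followed by "size dt dq" block triplets, last line a bare size, blank line
## terminating each chain. Target strand is always "+". Query-side "-"
## coordinates are normalized to forward-strand intervals on read.

#' Read a UCSC chain file
#'
#' Parses pairwise-alignment chains into block-level records. The block
#' arithmetic invariant (sum of sizes plus gaps reconstructs both spans) is
#' asserted for every chain; a violation is a format error.
#'
#' @param path chain file path.
#' @return A list of class `ChainSet`; each element is a `Chain`: a list with
#'   `chain_id`, `score`, `t_chrom`, `t_size`, `t_start`, `t_end`, `q_chrom`,
#'   `q_size`, `q_strand`, `q_start`, `q_end` (as printed), forward-strand
#'   `q_fwd_start`/`q_fwd_end`, and a `blocks` data.table of
#'   `(size, dt, dq)` with the target-side aligned block coordinates
#'   `t_block_start`/`t_block_end`.
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("read_chain: no such file: ", path)
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (!startsWith(line, "chain"))
      stop("read_chain: line ", i, ": expected chain header, got: ", line)
    h <- strsplit(line, "[ \t]+")[[1L]]
    if (length(h) != 13L)
      stop("read_chain: line ", i, ": malformed header (", length(h), " fields)")
    hd <- list(score = as.numeric(h[2L]),
               t_chrom = h[3L], t_size = as.numeric(h[4L]),
               t_strand = h[5L], t_start = as.numeric(h[6L]), t_end = as.numeric(h[7L]),
               q_chrom = h[8L], q_size = as.numeric(h[9L]),
               q_strand = h[10L], q_start = as.numeric(h[11L]), q_end = as.numeric(h[12L]),
               chain_id = h[13L])
    i <- i + 1L
    sizes <- numeric(); dts <- numeric(); dqs <- numeric()
    repeat {
      if (i > n) stop("read_chain: truncated chain ", hd$chain_id)
      bl <- trimws(lines[i])
      if (!nzchar(bl)) stop("read_chain: truncated chain ", hd$chain_id)
      f <- suppressWarnings(as.numeric(strsplit(bl, "[ \t]+")[[1L]]))
      if (anyNA(f)) stop("read_chain: line ", i, ": malformed block line")
      i <- i + 1L
      if (length(f) == 1L) {
        sizes <- c(sizes, f); dts <- c(dts, 0); dqs <- c(dqs, 0)
        break
      } else if (length(f) == 3L) {
        sizes <- c(sizes, f[1L]); dts <- c(dts, f[2L]); dqs <- c(dqs, f[3L])
      } else stop("read_chain: line ", i - 1L, ": malformed block line")
    }
    if (sum(sizes) + sum(dts) != hd$t_end - hd$t_start)
      stop("read_chain: chain ", hd$chain_id, ": target block arithmetic mismatch")
    if (sum(sizes) + sum(dqs) != hd$q_end - hd$q_start)
      stop("read_chain: chain ", hd$chain_id, ": query block arithmetic mismatch")
    if (any(sizes <= 0))
      stop("read_chain: chain ", hd$chain_id, ": non-positive block size")
    t_block_start <- hd$t_start + cumsum(c(0, head(sizes + dts, -1L)))
    blocks <- data.table(size = sizes, dt = dts, dq = dqs,
                         t_block_start = t_block_start,
                         t_block_end = t_block_start + sizes)
    if (identical(hd$q_strand, "-")) {
      hd$q_fwd_start <- hd$q_size - hd$q_end
      hd$q_fwd_end <- hd$q_size - hd$q_start
    } else {
      hd$q_fwd_start <- hd$q_start
      hd$q_fwd_end <- hd$q_end
    }
    ch <- c(hd, list(blocks = blocks))
    class(ch) <- "Chain"
    chains[[length(chains) + 1L]] <- ch
  }
  class(chains) <- "ChainSet"
  chains
}

#' Write a chain set to a UCSC chain file
#'
#' @param chains a `ChainSet` (as from [read_chain()] or [emit_chains()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %s %s %s %s %s %s %s %s %s %s %s %s",
                       format(ch$score, scientific = FALSE),
                       ch$t_chrom, format(ch$t_size, scientific = FALSE), ch$t_strand,
                       format(ch$t_start, scientific = FALSE),
                       format(ch$t_end, scientific = FALSE),
                       ch$q_chrom, format(ch$q_size, scientific = FALSE), ch$q_strand,
                       format(ch$q_start, scientific = FALSE),
                       format(ch$q_end, scientific = FALSE), ch$chain_id), con)
    b <- ch$blocks
    nb <- nrow(b)
    if (nb > 1L)
      writeLines(sprintf("%s %s %s",
                         format(b$size[-nb], scientific = FALSE),
                         format(b$dt[-nb], scientific = FALSE),
                         format(b$dq[-nb], scientific = FALSE)), con)
    writeLines(format(b$size[nb], scientific = FALSE), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @export
print.ChainSet <- function(x, ...) {
  cat(sprintf("ChainSet: %d chain(s)\n", length(x)))
  invisible(x)
}

#' Target-side aligned blocks of a chain
#'
#' @param chain a `Chain`.
#' @return data.table with 0-based half-open `start`/`end` on the target
#'   (human-side) genome.
#' @export
chain_target_blocks <- function(chain) {
  data.table(start = chain$blocks$t_block_start, end = chain$blocks$t_block_end)
}
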