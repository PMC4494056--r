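library(data.table)

## naive all-pairs interval intersection oracle
brute_intersect <- function(a, b, min_overlap_bp = 1L) {
  a <- as.data.table(a); b <- as.data.table(b)
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap_bp)
      out[[length(out) + 1L]] <- data.table(idx_a = i, idx_b = j,
                                            chrom = a$chrom[i],
                                            overlap_bp = as.integer(ov))
  }
  if (!length(out))
    return(data.table(idx_a = integer(), idx_b = integer(),
                      chrom = character(), overlap_bp = integer()))
  rbindlist(out)[order(idx_a, idx_b)]
}

## per-base chain coverage oracle: membership of every window base in any
## aligned block of the best single chain
brute_best_coverage <- function(w0, w1, chrom, chains) {
  best <- 0
  for (ch in chains) {
    if (!identical(ch$t_chrom, chrom)) next
    covered <- 0L
    for (p in w0:(w1 - 1L)) {
      b <- ch$blocks
      if (any(p >= b$t_block_start & p < b$t_block_end)) covered <- covered + 1L
    }
    best <- max(best, covered / (w1 - w0))
  }
  best
}

## naive exact-match scan (both strands, palindrome deduplicated)
brute_scan <- function(query, seqs) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  count1 <- function(q, s) {
    hits <- gregexpr(q, s, fixed = TRUE)[[1L]]
    n <- sum(hits > 0)
    # gregexpr skips overlapping matches; rescan manually
    n <- 0L
    Ls <- nchar(s); Lq <- nchar(q)
    if (Ls >= Lq)
      for (p in 1:(Ls - Lq + 1L))
        if (substr(s, p, p + Lq - 1L) == q) n <- n + 1L
    n
  }
  q <- toupper(query); rc <- revcomp(q)
  total <- 0L
  for (s in seqs) {
    s <- toupper(s)
    total <- total + count1(q, s)
    if (rc != q) total <- total + count1(rc, s)
  }
  total
}

## exhaustive mutant enumeration oracle (order 1)
brute_mutants <- function(seq, min_len, max_len) {
  chars <- strsplit(seq, "")[[1L]]
  cpos <- which(chars == "C")
  out <- character()
  for (p in cpos) for (w0 in seq_along(chars)) for (w1 in seq_along(chars)) {
    len <- w1 - w0 + 1L
    if (len < min_len || len > max_len) next
    if (p < w0 || p > w1) next
    m <- chars[w0:w1]
    m[p - w0 + 1L] <- "T"
    out <- c(out, paste(m, collapse = ""))
  }
  unique(out)
}

## upper-tail hypergeometric by binomial-coefficient summation
brute_hyper <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## consecutive-triple symbol oracle
brute_symbols <- function(calls, max_span) {
  calls <- as.data.table(calls)[kind == "hmC" & context == "CG"]
  out <- list()
  for (cc in unique(calls$chrom)) {
    d <- calls[chrom == cc][order(pos)]
    if (nrow(d) < 3L) next
    for (i in 1:(nrow(d) - 2L)) {
      s <- d$strand[i:(i + 2L)]
      if (s[1] == s[3] && s[2] != s[1] && d$pos[i + 2L] - d$pos[i] <= max_span)
        out[[length(out) + 1L]] <- data.table(chrom = cc, p1 = d$pos[i],
                                              p2 = d$pos[i + 1L],
                                              p3 = d$pos[i + 2L])
    }
  }
  if (!length(out)) return(data.table(chrom = character(), p1 = integer(),
                                      p2 = integer(), p3 = integer()))
  rbindlist(out)[order(chrom, p1)]
}

## random interval fixture
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L,
                             max_len = 300L) {
  start <- sample(max_pos, n, replace = TRUE)
  data.table(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample(max_len, n, replace = TRUE))
}

## one-chain fixture builder from explicit block triplets
make_chain <- function(blocks, t_chrom = "chr1", t_start = 0, q_chrom = "chr1",
                       q_strand = "+", q_start = 0, t_size = NULL,
                       q_size = NULL, id = "1") {
  sizes <- vapply(blocks, `[`, 0, 1L)
  dts <- vapply(blocks, `[`, 0, 2L)
  dqs <- vapply(blocks, `[`, 0, 3L)
  t_end <- t_start + sum(sizes) + sum(dts)
  q_end <- q_start + sum(sizes) + sum(dqs)
  if (is.null(t_size)) t_size <- t_end
  if (is.null(q_size)) q_size <- q_end
  lines <- c(sprintf("chain 1000 %s %d + %d %d %s %d %s %d %d %s",
                     t_chrom, t_size, t_start, t_end, q_chrom, q_size,
                     q_strand, q_start, q_end, id))
  nb <- length(sizes)
  if (nb > 1L)
    lines <- c(lines, sprintf("%d %d %d", sizes[-nb], dts[-nb], dqs[-nb]))
  lines <- c(lines, sprintf("%d", sizes[nb]), "")
  f <- tempfile(fileext = ".chain")
  writeLines(lines, f)
  read_chain(f)
}

## small deterministic cohort used by several test files
small_cohort <- function(seed = 11) {
  simulate_cohort(simulation_config(seed = seed))
}
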