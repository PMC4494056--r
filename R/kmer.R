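#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement matchPattern
NULL

#' Construct a seed oligonucleotide
#'
#' Records the C residues of a seed sequence (labelled C1..Cn in 5'-to-3'
#' order); these are the potential methylation/deamination positions the
#' mutant enumeration works over.
#'
#' @param sequence DNA string (ACGT only; case-insensitive).
#' @return list of class `SeedOligo` with `sequence`, `c_positions`
#'   (1-based indices), `labels`.
#' @export
seed_oligo <- function(sequence) {
  seq <- toupper(sequence)
  if (!grepl("^[ACGT]+$", seq)) stop("seed_oligo: sequence must be ACGT only")
  pos <- which(strsplit(seq, "")[[1L]] == "C")
  out <- list(sequence = seq, c_positions = pos,
              labels = if (length(pos)) paste0("C", seq_along(pos)) else character())
  class(out) <- "SeedOligo"
  out
}

#' Enumerate C-to-T mutant oligos of a seed
#'
#' For every substring window of the seed with length in
#' `[min_len, max_len]` and every C position inside that window, emits the
#' window sequence with that C replaced by T (`order = 1`); `order = 2` adds
#' every pair of C positions within a window. Identical mutant strings
#' arising from different (position, window) combinations are deduplicated,
#' keeping multi-label provenance.
#'
#' @param seed a `SeedOligo`.
#' @param min_len minimum window length (>= 8; the default 12 is the
#'   shortest length at which exact matches remain informative).
#' @param max_len maximum window length (<= seed length).
#' @param order 1 for single-site mutants, 2 to add double mutants.
#' @return data.table of class `MutantCatalog`: `sequence`, `length`,
#'   `labels` (comma-joined C labels of the mutated site(s)),
#'   `window_start` (1-based offset of the window within the seed),
#'   `n_provenance` (number of distinct (position, window) origins).
#' @export
enumerate_mutants <- function(seed, min_len = 12L, max_len = 24L, order = 1L) {
  stopifnot(inherits(seed, "SeedOligo"), order %in% c(1L, 2L))
  L <- nchar(seed$sequence)
  if (min_len < 1L) stop("enumerate_mutants: min_len must be >= 1")
  if (min_len < 8L)
    warning("enumerate_mutants: min_len < 8; short exact matches are ",
            "statistically uninformative")
  if (max_len > L) stop("enumerate_mutants: max_len exceeds seed length")
  if (!length(seed$c_positions)) {
    warning("enumerate_mutants: seed has no C residues")
    return(empty_catalog())
  }
  chars <- strsplit(seed$sequence, "")[[1L]]
  rows <- list()
  for (w0 in seq_len(L)) {
    for (len in min_len:max_len) {
      w1 <- w0 + len - 1L
      if (w1 > L) break
      cs <- which(seed$c_positions >= w0 & seed$c_positions <= w1)
      if (!length(cs)) next
      combs <- if (order == 1L) as.list(cs) else
        c(as.list(cs), if (length(cs) >= 2L) combn(cs, 2L, simplify = FALSE))
      for (cb in combs) {
        mut <- chars[w0:w1]
        mut[seed$c_positions[cb] - w0 + 1L] <- "T"
        rows[[length(rows) + 1L]] <- data.table(
          sequence = paste(mut, collapse = ""),
          length = len,
          labels = paste(seed$labels[cb], collapse = ","),
          window_start = w0,
          mut_order = length(cb))
      }
    }
  }
  cat <- rbindlist(rows)
  # dedup identical strings, keep provenance
  cat <- cat[, .(length = length[1L],
                 labels = paste(unique(labels), collapse = ";"),
                 window_start = window_start[1L],
                 mut_order = mut_order[1L],
                 n_provenance = .N), by = sequence]
  setattr(cat, "class", c("MutantCatalog", class(cat)))
  cat[]
}

empty_catalog <- function() {
  cat <- data.table(sequence = character(), length = integer(),
                    labels = character(), window_start = integer(),
                    mut_order = integer(), n_provenance = integer())
  setattr(cat, "class", c("MutantCatalog", class(cat)))
  cat
}

#' Count exact-match loci of queries in a genome
#'
#' Exact matching only: 100% identity, no gaps, case-insensitive; ambiguity
#' codes in the genome never match. Overlapping occurrences are counted
#' separately. With `strands = "both"`, reverse-complement hits at distinct
#' loci are added; a palindromic query's forward and reverse hits coincide
#' and are counted once.
#'
#' @param queries character vector of ACGT query sequences (or a
#'   `MutantCatalog`, whose `sequence` column is used).
#' @param genome a `DNAStringSet`, a named character vector of chromosome
#'   sequences, or a FASTA path.
#' @param strands `"both"` (default) or `"forward"`.
#' @return data.table with `query` and `n_loci`.
#' @export
scan_genome <- function(queries, genome, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (inherits(queries, "MutantCatalog")) queries <- queries$sequence
  if (!all(grepl("^[ACGTacgt]+$", queries)))
    stop("scan_genome: non-ACGT character in query")
  genome <- as_dnastringset(genome)
  counts <- integer(length(queries))
  for (qi in seq_along(queries)) {
    q <- Biostrings::DNAString(toupper(queries[qi]))
    rc <- Biostrings::reverseComplement(q)
    palindrome <- as.character(rc) == as.character(q)
    total <- 0L
    for (ci in seq_along(genome)) {
      subj <- genome[[ci]]
      total <- total + length(Biostrings::matchPattern(q, subj, fixed = TRUE))
      if (strands == "both" && !palindrome)
        total <- total + length(Biostrings::matchPattern(rc, subj, fixed = TRUE))
    }
    counts[qi] <- total
  }
  data.table(query = toupper(queries), n_loci = counts)
}

as_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("scan_genome: unsupported genome input")
}

#' Per-C-position locus totals from an order-1 scan
#'
#' Sums loci across window lengths for each single mutated C position and
#' reports the asymmetry between high- and low-count positions: positions
#' with totals above the overall median form the high group, the rest the
#' low group, and the ratio of the two group medians is reported.
#'
#' @param catalog an order-1 `MutantCatalog`.
#' @param counts the matching [scan_genome()] result.
#' @return list with `profile` (label, n_loci) and `asymmetry_ratio`.
#' @export
per_position_profile <- function(catalog, counts) {
  if (!nrow(catalog))
    return(list(profile = data.table(label = character(), n_loci = integer()),
                asymmetry_ratio = NA_real_))
  dt <- merge(as.data.table(catalog), counts, by.x = "sequence", by.y = "query")
  dt <- dt[mut_order == 1L & !grepl(";", labels)]
  prof <- dt[, .(n_loci = sum(n_loci)), by = .(label = labels)]
  prof <- prof[order(as.integer(sub("^C", "", label)))]
  med <- stats::median(prof$n_loci)
  hi <- prof[n_loci > med, n_loci]; lo <- prof[n_loci <= med, n_loci]
  ratio <- if (length(hi) && length(lo) && stats::median(lo) > 0)
    stats::median(hi) / stats::median(lo) else NA_real_
  list(profile = prof[], asymmetry_ratio = ratio)
}

#' Presence of query sequences across a set of genomes
#'
#' A query is present in a genome when it has at least one exact-match locus
#' (sequence-level presence; positional conservation through alignments is a
#' separate question and not attempted here).
#'
#' @param queries character vector of query sequences.
#' @param genomes named list of genomes (each as accepted by
#'   [scan_genome()]).
#' @param strands passed to [scan_genome()].
#' @return list with `matrix` (logical queries x genomes),
#'   `fraction_per_genome`, `fraction_in_all`.
#' @export
cross_genome_presence <- function(queries, genomes, strands = "both") {
  if (length(genomes) < 2L) stop("cross_genome_presence: need >= 2 genomes")
  pres <- sapply(genomes, function(g) scan_genome(queries, g, strands)$n_loci >= 1L)
  pres <- matrix(pres, nrow = length(queries),
                 dimnames = list(queries, names(genomes)))
  list(matrix = pres,
       fraction_per_genome = colMeans(pres),
       fraction_in_all = mean(rowSums(pres) == ncol(pres)))
}
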