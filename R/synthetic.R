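## Synthetic multi-species cohort with known ground truth.
##
## World model: a single random ancestral sequence; lineage-specific TE
## insertions on named branches (human; primate = all non-rodent panel
## members plus human; rodent; or any species' own branch). A species'
## genome is the ancestor with the insertions of its branch path applied.
## Pairwise chains (human as target) are exact by construction: every
## non-inserted base maps, lineage-specific insertions become dt/dq gaps.
## Binding-site windows planted inside human-branch insertions are
## therefore unliftable everywhere (the human-specific ground truth);
## windows inside primate-branch insertions fail only in rodents
## (primate-specific); windows in ancestral sequence lift everywhere
## (shared).

#' Simulation configuration
#'
#' Defaults encode the stated world: LADs covering 42.9% of the genome,
#' placental-style PMDs at 37%, a modern-human/Neanderthal split of 370,000
#' years within a ~75-Myr primate timeline, per-individual modern
#' conservation rates 31.4-43.6% and a low archaic rate, 5hmC adjacent to
#' 46%/21% of human-specific NANOG sites at 1-kb/100-bp windows, and a 3x
#' proximity excess near fast-evolving genes.
#'
#' @param seed RNG seed; identical configs give bit-identical outputs.
#' @param chromosomes named integer vector of chromosome lengths (bp).
#' @param primates non-human primate panel members.
#' @param rodents rodent panel members.
#' @param te_insertions named list `branch -> named count vector per TE
#'   family` (branches: `human`, `primate`, `rodent`, or a species name).
#' @param te_lengths named lengths of full-length family consensus (bp).
#' @param truncated_fraction fraction of L1-family copies inserted truncated.
#' @param te_divergence per-copy substitution rate applied to each inserted
#'   copy relative to its family consensus.
#' @param n_sites named per-TF site counts.
#' @param site_fractions named fractions `c(human_specific=, primate_specific=,
#'   shared=)`, must sum to 1.
#' @param window_bp binding-site window width.
#' @param lad_fraction,pmd_fraction target genome fractions (+/- 0.5%).
#' @param domain_length_bp characteristic planted domain length.
#' @param hmc_rate_1kb,hmc_rate_100bp fractions of human-specific NANOG
#'   sites with an adjacent 5hmC call within the 1-kb / 100-bp window
#'   (the 100-bp subset is nested in the 1-kb one).
#' @param symbol_rate fraction of human-specific NANOG sites with a planted
#'   three-letter 5hmC symbol inside the 1-kb window.
#' @param n_hmc_background background hmC calls scattered per chromosome.
#' @param genes_per_class planted fast- and slow-evolving gene counts.
#' @param proximity_effect fold excess of proximal sites near fast genes.
#' @param proximal_base_rate Poisson mean of proximal sites per slow gene.
#' @param proximity_threshold_bp planted proximity threshold.
#' @param conservation_rates named per-modern-individual presence rates.
#' @param archaic_rates named per-archaic-individual presence rates.
#' @param split_years modern/archaic split time (years).
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(
    seed = 1L,
    chromosomes = c(chr1 = 1000000L),
    primates = c("chimp", "gorilla", "orangutan", "gibbon", "rhesus", "marmoset"),
    rodents = c("mouse", "rat"),
    te_insertions = list(
      human = c(L1HS = 8L, LTR7 = 8L, LTR5_Hs = 6L),
      primate = c(L1PA2 = 10L, LTR7 = 6L),
      rodent = c(B1 = 4L)),
    te_lengths = c(L1HS = 6000L, L1PA2 = 6000L, LTR7 = 450L,
                   LTR5_Hs = 600L, B1 = 150L),
    truncated_fraction = 0.15,
    te_divergence = 0.005,
    n_sites = c(NANOG = 60L, CTCF = 40L, POU5F1 = 40L),
    site_fractions = c(human_specific = 0.3, primate_specific = 0.3,
                       shared = 0.4),
    window_bp = 200L,
    lad_fraction = 0.429,
    pmd_fraction = 0.37,
    domain_length_bp = 20000L,
    hmc_rate_1kb = 0.46,
    hmc_rate_100bp = 0.21,
    symbol_rate = 0.10,
    n_hmc_background = 40L,
    genes_per_class = c(fast = 12L, slow = 12L),
    proximity_effect = 3,
    proximal_base_rate = 2,
    proximity_threshold_bp = 10000L,
    conservation_rates = c(Papua = 0.314, Han = 0.357, Yoruba = 0.392,
                           French = 0.433, San = 0.436),
    archaic_rates = c(Nea1 = 0.015, Nea2 = 0.015, Nea3 = 0.015),
    split_years = 370000) {
  cfg <- as.list(environment())
  rates <- c(cfg$site_fractions, cfg$lad_fraction, cfg$pmd_fraction,
             cfg$hmc_rate_1kb, cfg$hmc_rate_100bp, cfg$symbol_rate,
             cfg$truncated_fraction, cfg$te_divergence,
             cfg$conservation_rates, cfg$archaic_rates)
  if (any(rates < 0 | rates > 1))
    stop("simulation_config: all rates must be in [0, 1]")
  if (abs(sum(cfg$site_fractions) - 1) > 1e-9)
    stop("simulation_config: site_fractions must sum to 1")
  if (cfg$split_years <= 0)
    stop("simulation_config: split_years must be positive")
  load <- sum(unlist(lapply(cfg$te_insertions, function(x)
    sum(cfg$te_lengths[names(x)] * x))))
  if (load > 0.5 * sum(cfg$chromosomes))
    stop("simulation_config: TE insertion load exceeds half the genome")
  class(cfg) <- "SimulationConfig"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_copy <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit)
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    seq <- paste(chars, collapse = "")
  }
  seq
}

branch_path <- function(species, cfg) {
  if (species == "human") c("human", "primate")
  else if (species %in% cfg$primates) c(species, "primate")
  else if (species %in% cfg$rodents) c(species, "rodent")
  else species
}

#' Simulate ancestral and derived genomes
#'
#' Draws the ancestral sequence and per-family consensus sequences, places
#' branch-specific TE insertions at well-separated ancestral positions, and
#' materializes one FASTA-able genome per species. Deterministic under the
#' config seed.
#'
#' @param config a `SimulationConfig`.
#' @return list of class `CohortGenomes`: `genomes` (named list of named
#'   character vectors, chromosome -> sequence; includes `human` and
#'   `ancestor`), `insertions` (data.table: event_id, branch, family, chrom,
#'   anc_pos, length, full_length), `consensus`, `config`.
#' @export
simulate_genomes <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  consensus <- lapply(cfg$te_lengths, random_dna)
  anc <- lapply(cfg$chromosomes, random_dna)
  events <- list()
  eid <- 0L
  for (branch in names(cfg$te_insertions)) {
    fams <- cfg$te_insertions[[branch]]
    for (fam in names(fams)) {
      for (k in seq_len(fams[[fam]])) {
        eid <- eid + 1L
        chrom <- sample(names(cfg$chromosomes), 1L)
        full_len <- cfg$te_lengths[[fam]]
        is_l1 <- grepl("^L1", fam)
        trunc <- is_l1 && stats::runif(1) < cfg$truncated_fraction
        len <- if (trunc)
          as.integer(round(full_len * stats::runif(1, 0.3, 0.9)))
        else full_len
        seq <- substr(consensus[[fam]], 1L, len)
        seq <- mutate_copy(seq, cfg$te_divergence)
        events[[eid]] <- data.table(
          event_id = eid, branch = branch, family = fam, chrom = chrom,
          anc_pos = NA_integer_, length = len, full_length = !trunc,
          sequence = seq)
      }
    }
  }
  ins <- rbindlist(events)
  if (!nrow(ins))
    ins <- data.table(event_id = integer(), branch = character(),
                      family = character(), chrom = character(),
                      anc_pos = integer(), length = integer(),
                      full_length = logical(), sequence = character())
  # well-separated ancestral positions per chromosome
  margin <- max(cfg$window_bp * 4L, 2000L)
  for (cc in unique(ins$chrom)) {
    idx <- which(ins$chrom == cc)
    L <- cfg$chromosomes[[cc]]
    span <- L - 2L * margin
    need <- length(idx)
    slots <- sort(sample(seq_len(max(span %/% margin, need)), need))
    ins$anc_pos[idx] <- as.integer(margin + slots * margin)
    if (any(ins$anc_pos[idx] > L - margin))
      stop("simulate_genomes: insertion load exceeds genome length")
  }
  setorder(ins, chrom, anc_pos)
  species <- c("human", cfg$primates, cfg$rodents)
  genomes <- c(list(ancestor = unlist(anc)),
               setNames(lapply(species, function(sp) {
                 path <- branch_path(sp, cfg)
                 vapply(names(cfg$chromosomes), function(cc) {
                   ev <- ins[chrom == cc & branch %in% path]
                   apply_insertions(anc[[cc]], ev)
                 }, "")
               }), species))
  out <- list(genomes = genomes,
              insertions = ins[, !"sequence"],
              insertion_seqs = ins$sequence,
              consensus = consensus,
              config = cfg)
  class(out) <- "CohortGenomes"
  out
}

apply_insertions <- function(anc_seq, ev) {
  if (!nrow(ev)) return(anc_seq)
  pieces <- character(2L * nrow(ev) + 1L)
  prev <- 0L
  for (i in seq_len(nrow(ev))) {
    pieces[2L * i - 1L] <- substr(anc_seq, prev + 1L, ev$anc_pos[i])
    pieces[2L * i] <- ev$sequence[i]
    prev <- ev$anc_pos[i]
  }
  pieces[2L * nrow(ev) + 1L] <- substr(anc_seq, prev + 1L, nchar(anc_seq))
  paste(pieces, collapse = "")
}

## species-coordinate offset of an ancestral position: anc_pos plus lengths
## of that species' insertions at strictly earlier ancestral positions
species_pos <- function(pos0, cc, species, cohort) {
  path <- branch_path(species, cohort$config)
  ev <- cohort$insertions[chrom == cc & branch %in% path & anc_pos < pos0]
  as.integer(pos0 + sum(ev$length))
}

#' Emit exact pairwise chains from simulated genomes
#'
#' For every non-human species, builds one chain per chromosome with the
#' human genome as target: shared (ancestral or common-branch) segments are
#' aligned blocks, human-side-only insertions are target gaps (dt),
#' species-side-only insertions are query gaps (dq). Also returns the
#' same-genome identity chains standing in for the alternate-assembly
#' uniqueness criterion.
#'
#' @param cohort a `CohortGenomes`.
#' @return list with `panel` (named list species -> `ChainSet`) and
#'   `alt_assembly` (identity `ChainSet` for human).
#' @export
emit_chains <- function(cohort) {
  cfg <- cohort$config
  species <- c(cfg$primates, cfg$rodents)
  human_path <- branch_path("human", cfg)
  panel <- setNames(lapply(species, function(sp) {
    sp_path <- branch_path(sp, cfg)
    chains <- list()
    for (cc in names(cfg$chromosomes)) {
      ev <- cohort$insertions[chrom == cc]
      ops <- list()  # (size, dt, dq) accumulation
      add_align <- function(n) if (n > 0) ops[[length(ops) + 1L]] <<- c(n, 0, 0)
      add_gap <- function(dt, dq) ops[[length(ops) + 1L]] <<- c(0, dt, dq)
      prev <- 0L
      for (i in seq_len(nrow(ev))) {
        add_align(ev$anc_pos[i] - prev)
        in_h <- ev$branch[i] %in% human_path
        in_s <- ev$branch[i] %in% sp_path
        if (in_h && in_s) add_align(ev$length[i])
        else if (in_h) add_gap(ev$length[i], 0)
        else if (in_s) add_gap(0, ev$length[i])
        prev <- ev$anc_pos[i]
      }
      add_align(cfg$chromosomes[[cc]] - prev)
      chains[[length(chains) + 1L]] <-
        ops_to_chain(ops, cc, nchar(cohort$genomes$human[[cc]]),
                     nchar(cohort$genomes[[sp]][[cc]]),
                     chain_id = paste0(sp, "_", cc))
    }
    class(chains) <- "ChainSet"
    chains
  }), species)
  alt <- lapply(names(cfg$chromosomes), function(cc) {
    L <- nchar(cohort$genomes$human[[cc]])
    ops_to_chain(list(c(L, 0, 0)), cc, L, L, chain_id = paste0("alt_", cc))
  })
  class(alt) <- "ChainSet"
  list(panel = panel, alt_assembly = alt)
}

ops_to_chain <- function(ops, chrom, t_size, q_size, chain_id) {
  # merge consecutive aligns and consecutive gaps into chain triplets
  sizes <- numeric(); dts <- numeric(); dqs <- numeric()
  cur_size <- 0; cur_dt <- 0; cur_dq <- 0; in_gap <- FALSE
  flush_block <- function() {
    sizes <<- c(sizes, cur_size); dts <<- c(dts, cur_dt); dqs <<- c(dqs, cur_dq)
    cur_size <<- 0; cur_dt <<- 0; cur_dq <<- 0
  }
  for (op in ops) {
    if (op[1L] > 0) {  # aligned run
      if (in_gap) { flush_block(); in_gap <- FALSE }
      cur_size <- cur_size + op[1L]
      if (cur_dt > 0 || cur_dq > 0) { } # not reachable: gaps close blocks
    } else {
      if (cur_size == 0) {
        # leading gap: absorb into chain start by shifting spans; the
        # simulator never produces one (chromosomes start ancestral)
        stop("ops_to_chain: leading gap unsupported")
      }
      cur_dt <- cur_dt + op[2L]; cur_dq <- cur_dq + op[3L]
      in_gap <- TRUE
    }
  }
  flush_block()
  t_start <- 0; q_start <- 0
  t_end <- sum(sizes) + sum(dts); q_end <- sum(sizes) + sum(dqs)
  stopifnot(t_end <= t_size, q_end <= q_size)
  t_block_start <- t_start + cumsum(c(0, head(sizes + dts, -1L)))
  ch <- list(score = sum(sizes), t_chrom = chrom, t_size = t_size,
             t_strand = "+", t_start = t_start, t_end = t_end,
             q_chrom = chrom, q_size = q_size, q_strand = "+",
             q_start = q_start, q_end = q_end, chain_id = chain_id,
             q_fwd_start = q_start, q_fwd_end = q_end,
             blocks = data.table(size = sizes, dt = dts, dq = dqs,
                                 t_block_start = t_block_start,
                                 t_block_end = t_block_start + sizes))
  class(ch) <- "Chain"
  ch
}
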