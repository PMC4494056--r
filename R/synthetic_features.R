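## Feature planting on the simulated cohort: binding sites with known
## lineage labels, LAD/PMD tilings at stated genome fractions, 5hmC calls
## adjacent to sites, gene sets with planted proximity enrichment.

#' Plant features with known ground truth on a simulated cohort
#'
#' Binding-site windows are placed fully inside human-branch insertions
#' (human-specific truth), fully inside primate-branch insertions
#' (primate-specific truth) or in ancestral sequence clear of any insertion
#' (shared truth). LAD and PMD tilings hit the configured genome fractions
#' within +/- 0.5%. CpG-context hmC calls are planted adjacent to the
#' configured fractions of human-specific NANOG sites, and a fast/slow gene
#' set carries the configured proximity excess.
#'
#' @param cohort a `CohortGenomes` from [simulate_genomes()].
#' @return list of class `CohortFeatures`: `sites` (BindingSites plus
#'   `truth_label`, `truth_family`), `lads`, `pmds` (IntervalSets),
#'   `methyl` (MethylCalls), `genes`, `proximal_sites`, `repeat_bed`
#'   (RepeatAnnotations for the human genome's insertions), `config`.
#' @export
plant_features <- function(cohort) {
  cfg <- cohort$config
  set.seed(cfg$seed + 1L)
  gs <- vapply(cohort$genomes$human, nchar, 0L)
  ins <- copy(cohort$insertions)
  ins[, human_start := vapply(seq_len(.N), function(i)
    species_pos(anc_pos[i], chrom[i], "human", cohort), 0L)]
  ins[, in_human := branch %in% branch_path("human", cfg)]

  sites <- rbindlist(lapply(names(cfg$n_sites), function(tf_name) {
    n <- cfg$n_sites[[tf_name]]
    n_h <- round(n * cfg$site_fractions[["human_specific"]])
    n_p <- round(n * cfg$site_fractions[["primate_specific"]])
    n_s <- n - n_h - n_p
    w <- cfg$window_bp
    # slot-based placement: site midpoints inside one TE copy are spaced at
    # least `spacing` apart so planted per-site signals (e.g. adjacent 5hmC
    # within 1-kb windows) cannot leak into a neighbouring site's window
    spacing <- 1100L
    place_in_branch <- function(k, branch_name, label) {
      if (k == 0L)
        return(data.table(chrom = character(), start = integer(),
                          end = integer(), truth_label = character(),
                          truth_family = character()))
      pool <- ins[branch == branch_name & length >= w + 40L]
      if (!nrow(pool)) stop("plant_features: no insertions fit branch ", branch_name)
      slots <- rbindlist(lapply(seq_len(nrow(pool)), function(i) {
        off <- seq(20L, pool$length[i] - w - 20L, by = spacing)
        data.table(off = off, chrom = pool$chrom[i],
                   human_start = pool$human_start[i],
                   family = pool$family[i])
      }))
      if (nrow(slots) < k)
        stop("plant_features: ", k, " ", label, " sites requested but only ",
             nrow(slots), " well-separated slots available in ", branch_name,
             "-branch insertions (config error)")
      picks <- slots[sample(.N, k)]
      data.table(chrom = picks$chrom,
                 start = picks$human_start + picks$off,
                 end = picks$human_start + picks$off + w,
                 truth_label = label, truth_family = picks$family)
    }
    h <- place_in_branch(n_h, "human", "human_specific")
    p <- place_in_branch(n_p, "primate", "primate_specific")
    s <- rbindlist(lapply(seq_len(n_s), function(i) {
      repeat {
        cc <- sample(names(gs), 1L)
        pos <- sample(seq(w, gs[[cc]] - 2L * w), 1L)
        near <- ins[chrom == cc & in_human == TRUE &
                      human_start < pos + 2L * w &
                      human_start + length > pos - w]
        if (!nrow(near))
          return(data.table(chrom = cc, start = pos, end = pos + w,
                            truth_label = "shared",
                            truth_family = NA_character_))
      }
    }))
    out <- rbindlist(list(h, p, s))
    out[, tf := tf_name]
    out
  }))
  bs <- binding_sites(interval_set(sites[, .(chrom, start, end)]),
                      tf = sites$tf, width = cfg$window_bp, genome_size = gs)
  bs[, truth_label := sites$truth_label]
  bs[, truth_family := sites$truth_family]

  lads <- tile_domains(gs, cfg$lad_fraction, cfg$domain_length_bp, phase = 0L)
  pmds <- tile_domains(gs, cfg$pmd_fraction, cfg$domain_length_bp,
                       phase = as.integer(cfg$domain_length_bp / 4))

  methyl <- plant_hmc(bs, cfg, gs)
  gene_out <- plant_genes(cfg, gs)

  human_ins <- ins[in_human == TRUE]
  repeat_bed <- data.table(
    chrom = human_ins$chrom, start = human_ins$human_start,
    end = human_ins$human_start + human_ins$length, strand = "+",
    repeat_name = human_ins$family,
    repeat_class = ifelse(grepl("^L1", human_ins$family), "LINE",
                          ifelse(grepl("^LTR", human_ins$family), "LTR", "SINE")),
    divergence_pct = cfg$te_divergence * 100,
    cons_begin = 1L, cons_end = human_ins$length, cons_left = 0L)
  setattr(repeat_bed, "class", c("RepeatAnnotations", class(repeat_bed)))

  out <- list(sites = bs[], lads = lads, pmds = pmds, methyl = methyl,
              genes = gene_out$genes, proximal_sites = gene_out$proximal_sites,
              repeat_bed = repeat_bed[], config = cfg)
  class(out) <- "CohortFeatures"
  out
}

## deterministic domain tiling at a target fraction: fixed-length domains on
## a regular period; achieved coverage is asserted within +/- 0.5%
tile_domains <- function(genome_size, fraction, domain_len, phase = 0L) {
  rows <- rbindlist(lapply(names(genome_size), function(cc) {
    L <- genome_size[[cc]]
    target <- round(L * fraction)
    n <- as.integer(ceiling(target / domain_len))
    lens <- rep(domain_len, n)
    lens[n] <- target - (n - 1L) * domain_len
    period <- L %/% n
    if (period <= domain_len)
      stop("tile_domains: fraction/length combination leaves no gaps")
    starts <- phase + (seq_len(n) - 1L) * period
    data.table(chrom = cc, start = starts, end = pmin(starts + lens, L))
  }))
  rows <- rows[end > start]
  out <- interval_set(rows, genome_size = genome_size)
  got <- genome_fraction(out)
  if (abs(got - fraction) > 0.005)
    stop(sprintf("tile_domains: achieved fraction %.4f misses target %.4f",
                 got, fraction))
  out
}

plant_hmc <- function(bs, cfg, gs) {
  calls <- list()
  hs_nanog <- bs[truth_label == "human_specific" & tf == "NANOG"]
  for (i in seq_len(nrow(hs_nanog))) {
    mid <- hs_nanog$midpoint[i]
    cc <- hs_nanog$chrom[i]
    u <- stats::runif(1)
    if (u < cfg$hmc_rate_100bp) off <- sample(c(-49:-5, 5:49), 1L)
    else if (u < cfg$hmc_rate_1kb) off <- sample(c(-499:-50, 50:499), 1L)
    else off <- NA_integer_
    if (!is.na(off))
      calls[[length(calls) + 1L]] <- data.table(
        chrom = cc, pos = mid + off, strand = "+", context = "CG",
        kind = "hmC", level_pct = 30)
    if (stats::runif(1) < cfg$symbol_rate) {
      d <- sample(seq(-440L, 400L), 1L)
      calls[[length(calls) + 1L]] <- data.table(
        chrom = cc, pos = mid + d + c(0L, 12L, 24L),
        strand = c("+", "-", "+"), context = "CG", kind = "hmC",
        level_pct = 30)
    }
  }
  for (cc in names(gs)) {
    n <- cfg$n_hmc_background
    calls[[length(calls) + 1L]] <- data.table(
      chrom = cc, pos = sort(sample(seq_len(gs[[cc]] - 1L), n)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      context = "CG", kind = "hmC", level_pct = 20)
  }
  out <- rbindlist(calls)[order(chrom, pos)]
  setattr(out, "class", c("MethylCalls", class(out)))
  out[]
}

plant_genes <- function(cfg, gs) {
  n_fast <- cfg$genes_per_class[["fast"]]
  n_slow <- cfg$genes_per_class[["slow"]]
  n <- n_fast + n_slow
  span <- 2000L
  thr0 <- cfg$proximity_threshold_bp
  # non-overlapping gene neighborhoods (span + 2 x threshold) so planted
  # proximal counts are attributable to exactly one gene
  slot <- span + 2L * thr0 + 1000L
  slots <- rbindlist(lapply(names(gs), function(c1)
    data.table(chrom = c1, slot_start = seq(0L, gs[[c1]] - slot, by = slot))))
  if (nrow(slots) < n)
    stop("plant_genes: genome too small for ", n,
         " non-overlapping gene neighborhoods")
  pick <- slots[sample(.N, n)]
  cc <- pick$chrom
  start <- pick$slot_start + thr0 + 500L
  genes <- data.table(
    gene_id = sprintf("gene_%03d", seq_len(n)),
    chrom = cc, start = start, end = start + span,
    class = rep(c("fast", "slow"), c(n_fast, n_slow)),
    ka_ks = c(stats::runif(n_fast, 0.6, 1.2), stats::runif(n_slow, 0.05, 0.3)))
  thr <- thr0
  prox <- rbindlist(lapply(seq_len(n), function(i) {
    lambda <- cfg$proximal_base_rate *
      if (genes$class[i] == "fast") cfg$proximity_effect else 1
    k <- stats::rpois(1L, lambda)
    if (!k) return(NULL)
    pos <- sample(seq(genes$start[i] - thr + 1L, genes$end[i] + thr - 1L), k)
    data.table(chrom = genes$chrom[i], midpoint = pos, planted_gene = genes$gene_id[i])
  }))
  if (is.null(prox) || !nrow(prox))
    prox <- data.table(chrom = character(), midpoint = integer(),
                       planted_gene = character())
  list(genes = genes[], proximal_sites = prox[])
}

#' Simulate per-individual presence of human-specific sites
#'
#' Each human-specific site is present in individual `i` independently with
#' that individual's configured conservation rate; archaic individuals use
#' the archaic rates. Deterministic under the config seed.
#'
#' @param features a `CohortFeatures` (or any table with `site_id` and
#'   `truth_label`).
#' @param config the `SimulationConfig`.
#' @return list with `individuals` (ready for [score_conservation()]),
#'   `true_rates`, `site_ids`.
#' @export
simulate_individual_presence <- function(features, config) {
  sites <- if (inherits(features, "CohortFeatures")) features$sites else features
  ids <- sites[sites$truth_label == "human_specific", ][["site_id"]]
  if (!length(ids)) stop("simulate_individual_presence: no human-specific sites")
  set.seed(config$seed + 2L)
  rates <- c(config$conservation_rates, config$archaic_rates)
  eras <- c(rep("modern", length(config$conservation_rates)),
            rep("archaic", length(config$archaic_rates)))
  individuals <- setNames(lapply(seq_along(rates), function(j) {
    calls <- stats::runif(length(ids)) < rates[[j]]
    names(calls) <- ids
    list(era = eras[j], calls = calls)
  }), names(rates))
  list(individuals = individuals, true_rates = rates, site_ids = ids)
}

#' Run the full synthetic cohort generator
#'
#' Genomes, chains, planted features and individual presence in one call;
#' optionally writes every artifact (FASTA, chain, BED, TSV and a
#' ground-truth table) to `outdir` deterministically.
#'
#' @param config a `SimulationConfig`.
#' @param outdir optional output directory.
#' @return list of class `SyntheticCohort` with `genomes`, `chains`,
#'   `features`, `presence`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), outdir = NULL) {
  genomes <- simulate_genomes(config)
  chains <- emit_chains(genomes)
  features <- plant_features(genomes)
  presence <- simulate_individual_presence(features, config)
  out <- list(genomes = genomes, chains = chains, features = features,
              presence = presence, config = config)
  class(out) <- "SyntheticCohort"
  if (!is.null(outdir)) write_cohort(out, outdir)
  out
}

write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(cohort$genomes$genomes)) {
    seqs <- Biostrings::DNAStringSet(cohort$genomes$genomes[[sp]])
    Biostrings::writeXStringSet(seqs, file.path(outdir, paste0(sp, ".fa")))
  }
  for (sp in names(cohort$chains$panel))
    write_chain(cohort$chains$panel[[sp]],
                file.path(outdir, paste0("human_", sp, ".chain")))
  write_chain(cohort$chains$alt_assembly, file.path(outdir, "human_alt.chain"))
  ft <- cohort$features
  write_bed(interval_set(ft$sites[, .(chrom, start = window_start,
                                      end = window_end, name = site_id)]),
            file.path(outdir, "site_windows.bed"))
  write_bed(ft$lads, file.path(outdir, "lads.bed"))
  write_bed(ft$pmds, file.path(outdir, "pmds.bed"))
  write_methyl(ft$methyl, file.path(outdir, "hmc.tsv"))
  write_tsv(ft$genes, file.path(outdir, "genes.tsv"))
  write_tsv(as.data.table(ft$repeat_bed), file.path(outdir, "repeats.tsv"))
  truth <- ft$sites[, .(site_id, tf, chrom, start, end, truth_label,
                        truth_family)]
  pres <- sapply(cohort$presence$individuals, function(x)
    as.integer(x$calls[truth[truth_label == "human_specific", site_id]]))
  write_tsv(truth, file.path(outdir, "ground_truth.tsv"))
  pres_dt <- data.table(site_id = truth[truth_label == "human_specific", site_id])
  for (nm in colnames(pres)) pres_dt[, (nm) := pres[, nm]]
  write_tsv(pres_dt, file.path(outdir, "presence.tsv"))
  invisible(outdir)
}
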