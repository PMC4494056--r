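#' Pipeline configuration
#'
#' Accepts an R list or a JSON file path. Recognized keys: `seed`, `outdir`,
#' `stages` (subset of simulate, classify, repeats, domains, proximity, hmc,
#' conserve, rates in any order; dependency order is enforced), `min_match`,
#' `window_bp`, `coloc_window_bp`, and `sim` (overrides passed through to
#' [simulation_config()]). Unknown keys are rejected.
#'
#' @param config list or JSON path.
#' @return validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  known <- c("seed", "outdir", "stages", "min_match", "window_bp",
             "coloc_window_bp", "sim")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    seed = 1L, outdir = NULL,
    stages = c("simulate", "classify", "repeats", "domains", "proximity",
               "hmc", "conserve", "rates"),
    min_match = 0.95, window_bp = 200L, coloc_window_bp = 10000L,
    sim = list())
  cfg <- utils::modifyList(defaults, as.list(config))
  deps <- list(classify = "simulate", repeats = "classify",
               domains = "classify", proximity = "classify",
               hmc = "classify", conserve = "classify", rates = character())
  for (st in cfg$stages) {
    need <- deps[[st]]
    miss <- setdiff(need, cfg$stages)
    if (length(miss))
      stop("pipeline_config: stage '", st, "' requires upstream stage(s): ",
           paste(miss, collapse = ", "))
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full pipeline on the synthetic cohort
#'
#' Stages run in dependency order (simulate, classify, then the
#' characterization stages, then rates). Each stage's table is written as a
#' TSV under `outdir` (when set) together with a manifest recording
#' completion state and a human-readable report; identical config and seed
#' give byte-identical outputs.
#'
#' @param config a `PipelineConfig`, list, or JSON path.
#' @return list of class `PipelineResult` with one element per executed
#'   stage plus `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "PipelineConfig")) config else pipeline_config(config)
  stage_order <- c("simulate", "classify", "repeats", "domains", "proximity",
                   "hmc", "conserve", "rates")
  stages <- stage_order[stage_order %in% cfg$stages]
  res <- list()
  manifest <- data.table(stage = stages, status = "pending", output = NA_character_)
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, dt) {
    if (is.null(outdir)) return(NA_character_)
    p <- file.path(outdir, paste0(name, ".tsv"))
    write_tsv(as.data.table(dt), p)
    basename(p)  # manifest records bundle-relative names
  }
  cohort <- NULL
  for (st in stages) {
    out_path <- NA_character_
    if (st == "simulate") {
      sim_cfg <- do.call(simulation_config, c(list(seed = cfg$seed), cfg$sim))
      cohort <- simulate_cohort(sim_cfg)
      res$simulate <- cohort
      out_path <- emit("sites_truth",
                       cohort$features$sites[, .(site_id, tf, chrom, start,
                                                 end, truth_label)])
    } else if (st == "classify") {
      cl <- classify_sites(cohort$features$sites, cohort$chains$panel,
                           alt_chains = cohort$chains$alt_assembly,
                           min_match = cfg$min_match)
      res$classify <- cl
      res$classify_summary <- classification_summary(cl)
      out_path <- emit("classification",
                       as.data.table(cl)[, .(site_id, tf, chrom, window_start,
                                             window_end, label)])
      emit("classification_summary", res$classify_summary)
    } else if (st == "repeats") {
      rep_rep <- annotate_repeat_overlap(res$classify[label == "human_specific"],
                                         cohort$features$repeat_bed)
      res$repeats <- rep_rep
      out_path <- emit("repeat_association", rep_rep$per_tf)
    } else if (st == "domains") {
      hs <- res$classify[label == "human_specific"]
      dom <- place_in_domains(hs, cohort$features$lads,
                              genome_size = attr(cohort$features$lads,
                                                 "genome_size", exact = TRUE))
      pmd <- pmd_colocalization(res$classify, cohort$features$pmds)
      res$domains <- list(lad_placement = dom, pmd = pmd)
      out_path <- emit("domains", data.table(
        domain_set = "lads", n_sites = dom$n_sites, n_inside = dom$n_inside,
        expected_inside = dom$expected_inside,
        genome_fraction = dom$genome_fraction, p_binomial = dom$p_binomial))
      emit("pmd_colocalization", pmd)
    } else if (st == "proximity") {
      thr <- compute_threshold(rep(cohort$config$proximity_threshold_bp, 2L))
      prox <- count_proximal(cohort$features$proximal_sites,
                             cohort$features$genes, thr)
      res$proximity <- prox
      res$proximity_cor <- correlate_with_rate(prox$records)
      out_path <- emit("proximity", prox$records[, .(gene_id, class, ka_ks,
                                                     n_proximal_sites,
                                                     associated)])
    } else if (st == "hmc") {
      hs <- res$classify[label == "human_specific"]
      hp <- hmc_proximity(hs, cohort$features$methyl)
      sym <- detect_symbols(cohort$features$methyl)
      res$hmc <- list(proximity = hp, symbols = sym,
                      coloc = symbol_colocalization(hs, sym))
      out_path <- emit("hmc_proximity", hp)
    } else if (st == "conserve") {
      hs <- res$classify[label == "human_specific" & tf == "NANOG"]
      cm <- score_conservation(hs, cohort$presence$individuals)
      res$conserve <- list(matrix = cm,
                           summary = cohort_summary(cm),
                           era = attribute_era(cm,
                                               cohort$config$split_years))
      out_path <- emit("conservation", res$conserve$summary$per_individual)
    } else if (st == "rates") {
      res$rates <- build_rate_table()
      out_path <- emit("rate_table", as.data.table(res$rates))
    }
    manifest[stage == st, `:=`(status = "done", output = out_path)]
  }
  res$manifest <- manifest[]
  if (!is.null(outdir)) {
    write_tsv(manifest, file.path(outdir, "manifest.tsv"))
    writeLines(make_report(res), file.path(outdir, "report.md"))
  }
  class(res) <- "PipelineResult"
  res
}

#' Render a human-readable pipeline report
#'
#' Markdown tables mirroring the pipeline's summary shapes (classification
#' funnel, repeat association, domain placement, creation rates); every
#' percentage is recomputed from the underlying counts, never copied.
#'
#' @param result a `PipelineResult`.
#' @return character vector of markdown lines.
#' @export
make_report <- function(result) {
  lines <- c("# Pipeline report", "")
  fmt_pct <- function(k, n, digits = 1) {
    ifelse(n > 0, sprintf(paste0("%.", digits, "f"), 100 * k / n), "NA")
  }
  if (!is.null(result$classify_summary)) {
    s <- result$classify_summary
    lines <- c(lines, "## Site classification", "",
               "| TF | total | primate-specific (%) | human-specific (%) |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %d (%s) | %d (%s) |", s$tf, s$n_total,
                       s$n_primate_specific,
                       fmt_pct(s$n_primate_specific, s$n_total, 0),
                       s$n_human_specific,
                       fmt_pct(s$n_human_specific, s$n_total, 1)), "")
  } else lines <- c(lines, "## Site classification", "", "not run", "")
  if (!is.null(result$repeats)) {
    r <- result$repeats$per_tf
    lines <- c(lines, "## Repeat association (human-specific sites)", "",
               "| TF | sites | within repeats (%) | LTR/LINE (%) |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %d (%s) | %d (%s) |", r$tf, r$n_sites,
                       r$n_in_repeats, fmt_pct(r$n_in_repeats, r$n_sites),
                       r$n_in_ltr_line, fmt_pct(r$n_in_ltr_line, r$n_sites)),
               "")
  } else lines <- c(lines, "## Repeat association", "", "not run", "")
  if (!is.null(result$domains)) {
    d <- result$domains$lad_placement
    lines <- c(lines, "## LAD placement", "",
               sprintf("%d of %d sites inside LADs; expected %.1f under the %.1f%% random model (binomial p = %.3g)",
                       d$n_inside, d$n_sites, d$expected_inside,
                       100 * d$genome_fraction, d$p_binomial), "")
  } else lines <- c(lines, "## LAD placement", "", "not run", "")
  if (!is.null(result$conserve)) {
    cs <- result$conserve$summary
    er <- result$conserve$era
    lines <- c(lines, "## Individual-genome conservation", "",
               sprintf("conserved in all moderns: %d/%d (%s%%); in any: %s%%; post-split: %d/%d",
                       cs$n_in_all, cs$n_sites, fmt_pct(cs$n_in_all, cs$n_sites),
                       fmt_pct(cs$n_in_any, cs$n_sites),
                       er$n_post_split, er$n_assessable), "")
  } else lines <- c(lines, "## Individual-genome conservation", "", "not run", "")
  if (!is.null(result$rates)) {
    rt <- as.data.table(result$rates)
    lines <- c(lines, "## Creation rates", "",
               "| TF | lineage | novel | per 100k yr | yr per site | accel |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %d | %.2f | %s | %s |", rt$tf, rt$lineage,
                       rt$n_novel, rt$rate_per_100k,
                       ifelse(is.na(rt$years_disp), "NA",
                              format(rt$years_disp, scientific = FALSE)),
                       ifelse(is.na(rt$accel_disp), "-",
                              sprintf("%.1f", rt$accel_disp))), "")
  } else lines <- c(lines, "## Creation rates", "", "not run", "")
  lines
}
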