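# End-to-end pipeline driver: simulate -> census -> compare -> targets ->
# enrich -> stats, with fixed seeds, per-stage TSV outputs, a YAML
# provenance record and a plain-text report.

#' Pipeline configuration
#'
#' @param seed global RNG seed; every stage derives its seeds from it.
#' @param outdir output directory for stage TSVs, provenance and report.
#' @param stages named logical vector toggling stages.
#' @param n_reads reads per simulated library.
#' @param total normalization library size.
#' @param max_shift mature terminus shift tolerance (nt).
#' @param energy_cutoff site energy cutoff (kcal/mol).
#' @param score_cutoff complementarity score threshold.
#' @param alpha enrichment significance level.
#' @param panel_k representative panel size.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("pollenmir_run_"),
                            stages = c(simulate = TRUE, census = TRUE,
                                       compare = TRUE, targets = TRUE,
                                       enrich = TRUE, stats = TRUE),
                            n_reads = 4000L, total = 1e7, max_shift = 2L,
                            energy_cutoff = -17, score_cutoff = 140,
                            alpha = 0.05, panel_k = 16L) {
  defaults <- c(simulate = TRUE, census = TRUE, compare = TRUE,
                targets = TRUE, enrich = TRUE, stats = TRUE)
  defaults[names(stages)] <- stages
  if (energy_cutoff > 0) stop("energy cutoff must be <= 0 kcal/mol")
  if (total <= 0) stop("total must be positive")
  structure(list(seed = as.integer(seed), outdir = outdir,
                 stages = defaults, n_reads = as.integer(n_reads),
                 total = total, max_shift = as.integer(max_shift),
                 energy_cutoff = energy_cutoff, score_cutoff = score_cutoff,
                 alpha = alpha, panel_k = as.integer(panel_k)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  do.call(pipeline_config, y)
}

check_dag <- function(stages) {
  needs <- list(census = "simulate", compare = "census",
                targets = c("simulate", "compare"), enrich = "targets")
  for (st in names(needs)) {
    if (stages[[st]] && !all(stages[needs[[st]]]))
      stop(sprintf("stage '%s' requires stage(s) %s to be enabled",
                   st, paste(needs[[st]], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a royal-jelly-like (animal-dominated), a beebread-like and a
#' pollen-like (plant-dominated) small-RNA library, runs the census on each,
#' compares plant-miRNA profiles and selects the representative panel, scans
#' synthetic mRNAs (one of which carries a planted miR162a site) with both
#' target predictors, tests GO enrichment of the called targets against a
#' synthetic annotation, and computes the phenotype and qPCR statistics.
#' Deterministic under `config$seed`; writes per-stage TSVs, a YAML
#' provenance record and a human-readable report to `config$outdir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of class `pipeline_result` with all stage
#'   outputs and the paths written.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  check_dag(config$stages)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(config$outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sim_mix <- c(royal_jelly = 0.10, beebread = 0.85, pollen = 0.90)
  if (config$stages[["simulate"]]) stage("simulate", {
    cfg0 <- sim_config(seed = config$seed, n_reads = config$n_reads)
    res$bundle <- gen_references(cfg0)
    # demo wiring: genuine binding sites planted into the first mRNAs
    # (gene 2 carries sites for two distinct miRNAs).  Only matures of
    # >= 21 nt can reach the default score threshold (140 = perfect 21-mer),
    # so the planted ids are picked by length.
    plant_site <- function(mrna, mirna_id, at) {
      site <- rev_comp(mature_seq(res$bundle, mirna_id))
      paste0(substr(mrna, 1, at - 1), site,
             substr(mrna, at + nchar(site), nchar(mrna)))
    }
    mat <- res$bundle$matures
    long_ids <- mat$mature_id[mat$kingdom == "plant" &
                                (mat$end - mat$start + 1L) >= 21L]
    long_ids <- unique(c("miR162a", long_ids))
    long_ids <- rep_len(long_ids, 4L)
    res$bundle$mrnas[1] <- plant_site(res$bundle$mrnas[1], long_ids[1], 101)
    res$bundle$mrnas[2] <- plant_site(res$bundle$mrnas[2], long_ids[2], 61)
    res$bundle$mrnas[2] <- plant_site(res$bundle$mrnas[2], long_ids[3], 161)
    res$bundle$mrnas[3] <- plant_site(res$bundle$mrnas[3], long_ids[4], 81)
    # one abundance spectrum shared by all samples, so beebread and pollen
    # profiles correlate the way real repeated sampling of one source does
    set.seed(config$seed + 7777L)
    abund <- setNames(stats::rlnorm(nrow(res$bundle$matures), 0, 1.2),
                      res$bundle$matures$mature_id)
    res$reads <- lapply(seq_along(sim_mix), function(i) {
      cfg <- sim_config(seed = config$seed + i,
                        n_reads = config$n_reads,
                        kingdom_mix = c(plant = unname(sim_mix[i])),
                        mirna_abundance = abund)
      gen_reads(res$bundle, cfg, sample_id = names(sim_mix)[i])
    })
    names(res$reads) <- names(sim_mix)
    write_bundle(res$bundle, file.path(config$outdir, "references"))
    for (sm in names(res$reads))
      write_fastq(res$reads[[sm]],
                  file.path(config$outdir, paste0(sm, ".fastq")))
  })

  if (config$stages[["census"]]) stage("census", {
    res$censuses <- lapply(names(res$reads), function(sm)
      census(res$reads[[sm]], res$bundle,
             max_shift = config$max_shift, total = config$total,
             sample_id = sm))
    names(res$censuses) <- names(res$reads)
    all_counts <- do.call(rbind, lapply(res$censuses, `[[`, "counts"))
    wr(all_counts, "count_table.tsv")
    hist <- do.call(rbind, lapply(names(res$censuses), function(sm)
      cbind(sample_id = sm, res$censuses[[sm]]$histogram)))
    wr(hist, "length_histogram.tsv")
  })

  if (config$stages[["compare"]]) stage("compare", {
    prof <- mirna_profiles(res$censuses, "plant")
    res$profiles <- prof
    res$detected <- lapply(prof, detect_types)
    res$correlation <- tryCatch(
      correlate_profiles(prof$beebread, prof$pollen), error = function(e) NA)
    res$panel <- select_representative(prof[c("beebread", "pollen")],
                                       k = config$panel_k)
    wr(data.frame(rank = seq_along(res$panel$panel),
                  mature_id = res$panel$panel), "panel.tsv")
    ov <- overlap_sets(res$detected$beebread, res$detected$pollen)
    wr(data.frame(comparison = "beebread_vs_pollen", t(ov)), "overlap.tsv")
  })

  if (config$stages[["targets"]]) stage("targets", {
    mat <- res$bundle$matures
    panel_ids <- intersect(res$panel$panel,
                           mat$mature_id[mat$kingdom == "plant"])
    panel_seqs <- setNames(
      vapply(panel_ids, function(id) mature_seq(res$bundle, id),
             character(1)), panel_ids)
    res$targets <- predict_targets(
      panel_seqs, res$bundle$mrnas,
      score_params = miranda_params(threshold = config$score_cutoff),
      cutoff = config$energy_cutoff)
    wr(as.data.frame(res$targets), "target_predictions.tsv")
  })

  if (config$stages[["enrich"]]) stage("enrich", {
    bg <- names(res$bundle$mrnas)
    tg <- unique(res$targets$gene_id)
    res$enrichment <- NULL
    if (length(tg)) {
      ann <- gen_annotations(bg, tg, seed = config$seed)
      mp <- map_orthologs(tg, ann$orthologs)
      bg_fly <- map_orthologs(bg, ann$orthologs)$mapped
      res$enrichment <- enrich_chisq(mp$mapped, bg_fly, ann$annotations,
                                     alpha = config$alpha)
      wr(as.data.frame(res$enrichment), "go_enrichment.tsv")
      if (any(res$enrichment$enriched)) {
        net <- export_network(res$enrichment, ann$annotations, mp$mapped)
        wr(net$edges, "go_network_edges.tsv")
      }
    }
  })

  if (config$stages[["stats"]]) stage("stats", {
    spec <- honeybee_effect_specs("mirna_pool")
    pheno <- gen_phenotypes(spec, n_per_arm = 30L, seed = config$seed)
    res$phenotypes <- pheno
    res$comparisons <- lapply(spec$trait, function(tr)
      compare_groups(pheno, tr))
    names(res$comparisons) <- spec$trait
    wr(do.call(rbind, lapply(res$comparisons, function(gc)
      data.frame(trait = gc$trait, test = gc$test,
                 statistic = gc$statistic, p = gc$p,
                 effect_abs = gc$effect_abs, effect_pct = gc$effect_pct))),
      "phenotype_stats.tsv")
    curve_true <- list(slope = -3.3219, intercept = 38)
    plate <- gen_qpcr(curve_true, true_amounts = c(0.05, 0.02, 5, 20),
                      noise_sd = 0.15, seed = config$seed)
    res$curve <- fit_standard_curve(plate[plate$role == "standard", ])
    unk <- plate[plate$role == "unknown", ]
    unk$est_amount <- absolute_quant(unk$ct, res$curve)
    res$qpcr <- unk
    wr(unk, "qpcr_absolute.tsv")
    ddplate <- gen_qpcr_relative(true_fold = 0.4, seed = config$seed)
    res$ddct <- relative_ddct(ddplate, "amTOR", "amActin")
    wr(res$ddct, "qpcr_ddct.tsv")
  })

  # provenance + report
  prov <- list(package = "pollenmir",
               version = as.character(packageVersion("pollenmir")),
               seed = config$seed,
               parameters = config[c("n_reads", "total", "max_shift",
                                     "energy_cutoff", "score_cutoff",
                                     "alpha", "panel_k")],
               stages = as.list(config$stages))
  yaml::write_yaml(prov, file.path(config$outdir, "provenance.yaml"))
  report <- write_report(res)
  writeLines(report, file.path(config$outdir, "report.txt"))
  res$report <- report
  res$paths <- paths
  class(res) <- "pipeline_result"
  invisible(res)
}

#' Render the plain-text pipeline report
#'
#' @param res a partially or fully populated `pipeline_result` list.
#' @return character vector of report lines.
#' @export
write_report <- function(res) {
  cfg <- res$config
  ln <- c("pollenmir pipeline report",
          strrep("=", 25),
          sprintf("seed: %d", cfg$seed), "")
  if (!is.null(res$censuses)) {
    ln <- c(ln, "Census", strrep("-", 6))
    for (sm in names(res$censuses)) {
      cn <- res$censuses[[sm]]
      ln <- c(ln, sprintf(
        "%s: %d reads in, %d clean; normalized sum = %.0f (target %.0f)",
        sm, cn$n_input, cn$n_clean, sum(cn$counts$normalized), cn$total))
    }
    ln <- c(ln, "")
  }
  if (!is.null(res$detected)) {
    ln <- c(ln, "Profiles", strrep("-", 8))
    for (sm in names(res$detected))
      ln <- c(ln, sprintf("%s: %d plant miRNA types detected", sm,
                          length(res$detected[[sm]])))
    if (!is.null(res$correlation) && is.finite(res$correlation))
      ln <- c(ln, sprintf("Pearson r (beebread vs pollen, log10(x+1)): %.3f",
                          res$correlation))
    if (!is.null(res$panel))
      ln <- c(ln, sprintf("panel (k=%d): %s", res$panel$k,
                          paste(res$panel$panel, collapse = ", ")))
    ln <- c(ln, "")
  }
  if (!is.null(res$targets)) {
    ln <- c(ln, "Target screen", strrep("-", 13),
            sprintf("energy cutoff: %.1f kcal/mol; score threshold: %.0f",
                    cfg$energy_cutoff, cfg$score_cutoff),
            sprintf("%d site(s) across %d gene(s)",
                    nrow(res$targets),
                    length(unique(res$targets$gene_id))), "")
  }
  if (!is.null(res$enrichment)) {
    ln <- c(ln, "GO enrichment", strrep("-", 13),
            sprintf("%d/%d terms enriched at alpha = %.2f",
                    sum(res$enrichment$enriched), nrow(res$enrichment),
                    cfg$alpha), "")
  }
  if (!is.null(res$comparisons)) {
    ln <- c(ln, "Phenotype statistics", strrep("-", 20))
    for (gc in res$comparisons)
      ln <- c(ln, sprintf("%s: %s = %.2f, p = %.4g, effect %+.2f (%+.2f%%)",
                          gc$trait, if (gc$test == "t") "t" else "F",
                          gc$statistic, gc$p, gc$effect_abs, gc$effect_pct))
    if (!is.null(res$curve))
      ln <- c(ln, sprintf(
        "standard curve: slope %.3f, R2 %.4f, efficiency %.0f%%",
        res$curve$slope, res$curve$r2, 100 * res$curve$efficiency))
    if (!is.null(res$ddct))
      ln <- c(ln, sprintf("ddCt mean fold (treated): %.3f",
                          attr(res$ddct, "arm_means")[["treated"]]))
  }
  ln
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
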