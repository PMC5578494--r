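# Synthetic-data generators.  Every input the pipeline consumes can be
# produced here with known ground truth: two-kingdom reference transcripts,
# miRNA precursors with mature coordinates, small-RNA read libraries with
# per-read truth labels, phenotype tables, and qPCR plates.

# The 16 plant miRNAs with the highest abundance in beebread and pollen,
# used as the default mature panel.  miR162a carries its canonical mature
# sequence; the remaining matures are simulated.
PLANT_PANEL <- c("miR156a", "miR157a", "miR158a", "miR160a", "miR162a",
                 "miR166a", "miR166g", "miR167a", "miR168a", "miR172a",
                 "miR172c", "miR390a", "miR397a", "miR403", "miR824",
                 "miR845a")

#' Canonical plant miR162a mature sequence
#' @param alphabet "rna" (default) or "dna".
#' @return the 21-nt mature sequence, 5'->3'.
#' @export
mir162a_sequence <- function(alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  s <- "UCGAUAAACCUCUGCAUCCAG"
  if (alphabet == "dna") as_dna(s) else s
}

#' Simulation configuration
#'
#' Bundles every knob of the read simulator.  Defaults reproduce the library
#' structure of the study system: insert lengths of degradation fragments
#' span 13-28 nt, miRNA-derived inserts 19-24 nt, and reads are emitted in
#' the DNA alphabet with a 3' sequencing adapter appended.
#'
#' @param seed integer RNG seed.
#' @param n_reads reads per sample.
#' @param kingdom_mix fraction of reads whose true source is a plant
#'   transcript/miRNA (the remainder is animal-derived).
#' @param mirna_abundance optional named non-negative weights over mature
#'   ids (sum-normalized); default uniform within each kingdom.
#' @param degradation_fraction fraction of reads that are tRNA/rRNA/mRNA
#'   degradation fragments rather than miRNAs.
#' @param fragment_length_range nt interval for degradation fragments.
#' @param mirna_length_range nt interval for simulated mature miRNAs.
#' @param adapter 3' adapter appended to each insert (DNA alphabet).
#' @param read_length sequencer read length (cycles); inserts shorter than
#'   this show a truncated adapter.
#' @param shift_probs named vector of probabilities for the terminus jitter
#'   of miRNA-derived reads; names are absolute shifts ("0","1","2","3"),
#'   mass at k > 0 is split evenly between +k and -k, drawn independently
#'   for each terminus.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reads = 10000L,
                       kingdom_mix = c(plant = 0.5),
                       mirna_abundance = NULL,
                       degradation_fraction = 0.3,
                       fragment_length_range = c(13L, 28L),
                       mirna_length_range = c(19L, 24L),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 36L,
                       shift_probs = c("0" = 0.70, "1" = 0.20,
                                       "2" = 0.08, "3" = 0.02)) {
  plant_frac <- unname(kingdom_mix[1])
  if (plant_frac < 0 || plant_frac > 1)
    stop("kingdom_mix must be a fraction in [0, 1]")
  if (degradation_fraction < 0 || degradation_fraction > 1)
    stop("degradation_fraction must be in [0, 1]")
  chk_range <- function(r, what) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 9 || r[2] > 33)
      stop(sprintf("%s must be a non-empty interval within [9, 33] nt", what))
    as.integer(r)
  }
  fragment_length_range <- chk_range(fragment_length_range,
                                     "fragment_length_range")
  mirna_length_range <- chk_range(mirna_length_range, "mirna_length_range")
  if (!is.null(mirna_abundance) && any(mirna_abundance < 0))
    stop("abundance weights must be non-negative")
  if (nchar(adapter) < 6) stop("adapter must be at least 6 nt")
  if (abs(sum(shift_probs) - 1) > 1e-8)
    stop("shift_probs must sum to 1")
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 plant_frac = plant_frac,
                 mirna_abundance = mirna_abundance,
                 degradation_fraction = degradation_fraction,
                 fragment_length_range = fragment_length_range,
                 mirna_length_range = mirna_length_range,
                 adapter = toupper(adapter),
                 read_length = as.integer(read_length),
                 shift_probs = shift_probs),
            class = "sim_config")
}

#' Reference bundle constructor with invariant checks
#'
#' @param plant_transcripts,animal_transcripts named character vectors of
#'   transcript sequences (decoy tRNA/rRNA/mRNA sources for degradation
#'   fragments).
#' @param precursors named character vector of miRNA precursor sequences.
#' @param matures data frame with columns `precursor_id`, `mature_id`,
#'   `start`, `end` (1-based inclusive on the precursor) and `kingdom`
#'   ("plant" or "animal").
#' @param mrnas named character vector of mRNA sequences for target scanning.
#' @return an object of class `reference_bundle`.
#' @export
reference_bundle <- function(plant_transcripts, animal_transcripts,
                             precursors, matures, mrnas = character(0)) {
  all_ids <- c(names(plant_transcripts), names(animal_transcripts),
               names(precursors), names(mrnas))
  if (anyDuplicated(all_ids)) stop("reference ids must be unique")
  for (s in list(plant_transcripts, animal_transcripts, precursors, mrnas))
    if (length(s)) check_rna(s, "reference sequence")
  stopifnot(all(c("precursor_id", "mature_id", "start", "end", "kingdom")
                %in% names(matures)))
  if (anyDuplicated(matures$mature_id)) stop("mature ids must be unique")
  plen <- nchar(precursors)[match(matures$precursor_id, names(precursors))]
  if (anyNA(plen)) stop("mature annotation references unknown precursor")
  ok <- matures$start >= 1 & matures$start <= matures$end &
    matures$end <= plen
  if (!all(ok))
    stop(sprintf("mature interval outside its precursor: %s",
                 paste(matures$mature_id[!ok], collapse = ", ")))
  structure(list(plant_transcripts = plant_transcripts,
                 animal_transcripts = animal_transcripts,
                 precursors = precursors, matures = matures, mrnas = mrnas),
            class = "reference_bundle")
}

#' Extract a mature miRNA sequence from its precursor
#' @param bundle a [reference_bundle()].
#' @param mature_id mature id present in `bundle$matures`.
#' @return the mature sequence (same alphabet as the precursor).
#' @export
mature_seq <- function(bundle, mature_id) {
  r <- bundle$matures[bundle$matures$mature_id == mature_id, ]
  substr(bundle$precursors[[r$precursor_id]], r$start, r$end)
}

#' Generate a synthetic two-kingdom reference bundle
#'
#' Builds plant and animal miRNA precursors (matures embedded at known
#' coordinates), decoy transcripts for degradation fragments, and mRNAs for
#' target scanning.  The plant mature panel defaults to the 16 high-abundance
#' beebread/pollen miRNAs (miR156a ... miR845a); miR162a gets its canonical
#' sequence, everything else is simulated.  Deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param n_plant_mirnas number of plant matures (first 16 take the panel
#'   names).
#' @param n_animal_mirnas number of animal (bee) matures.
#' @param n_transcripts decoy transcripts per kingdom.
#' @param n_mrnas mRNAs for target scanning.
#' @param flank_range precursor flank length interval around the mature.
#' @return a [reference_bundle()].
#' @export
gen_references <- function(config = sim_config(), n_plant_mirnas = 16L,
                           n_animal_mirnas = 10L, n_transcripts = 12L,
                           n_mrnas = 8L, flank_range = c(20L, 45L)) {
  stopifnot(inherits(config, "sim_config"))
  lr <- config$mirna_length_range
  if (lr[2] < nchar(mir162a_sequence()) && n_plant_mirnas >= 5)
    stop("mirna_length_range cannot host the canonical miR162a mature")
  set.seed(config$seed)
  plant_names <- if (n_plant_mirnas <= length(PLANT_PANEL))
    PLANT_PANEL[seq_len(n_plant_mirnas)]
  else c(PLANT_PANEL,
         sprintf("miR9%02da", seq_len(n_plant_mirnas - length(PLANT_PANEL))))
  animal_names <- sprintf("ame-miR-%d", seq(2, by = 37,
                                            length.out = n_animal_mirnas))
  make_precursors <- function(ids, kingdom, prefix) {
    n <- length(ids)
    mat_len <- sample(lr[1]:lr[2], n, replace = TRUE)
    seqs <- random_seq(n, mat_len)
    if (kingdom == "plant" && "miR162a" %in% ids) {
      seqs[ids == "miR162a"] <- mir162a_sequence()
      mat_len[ids == "miR162a"] <- nchar(mir162a_sequence())
    }
    fl5 <- sample(flank_range[1]:flank_range[2], n, replace = TRUE)
    fl3 <- sample(flank_range[1]:flank_range[2], n, replace = TRUE)
    pre <- paste0(random_seq(n, fl5), seqs, random_seq(n, fl3))
    names(pre) <- paste0(prefix, ids)
    data_frame <- data.frame(precursor_id = names(pre), mature_id = ids,
                             start = fl5 + 1L, end = fl5 + mat_len,
                             kingdom = kingdom, stringsAsFactors = FALSE)
    list(pre = pre, mat = data_frame)
  }
  pl <- make_precursors(plant_names, "plant", "pre-")
  an <- make_precursors(animal_names, "animal", "pre-")
  tr_len <- function() sample(200:900, n_transcripts, replace = TRUE)
  plant_tr <- setNames(random_seq(n_transcripts, tr_len()),
                       sprintf("plant_tx%02d", seq_len(n_transcripts)))
  animal_tr <- setNames(random_seq(n_transcripts, tr_len()),
                        sprintf("bee_tx%02d", seq_len(n_transcripts)))
  mrnas <- setNames(random_seq(n_mrnas, sample(400:900, n_mrnas,
                                               replace = TRUE)),
                    sprintf("bee_mRNA%02d", seq_len(n_mrnas)))
  reference_bundle(plant_tr, animal_tr, c(pl$pre, an$pre),
                   rbind(pl$mat, an$mat), mrnas)
}

#' Simulate a small-RNA read library with truth labels
#'
#' Each read is either a miRNA-derived insert (a mature sequence with
#' independent 5'/3' terminus jitter drawn from `config$shift_probs`,
#' clamped to the precursor) or a degradation fragment (uniform substring of
#' a decoy transcript).  The 3' adapter is appended and the read truncated to
#' `config$read_length`, as a sequencer would.  Reads are DNA-alphabet.
#'
#' @param bundle a [reference_bundle()].
#' @param config a [sim_config()].
#' @param sample_id label recorded in read ids.
#' @return a `read_set` data frame with columns `id`, `sequence`, `length`
#'   and hidden-truth columns `truth_class` (plant_miRNA, animal_miRNA,
#'   plant_fragment, animal_fragment), `truth_source`, `shift5`, `shift3`,
#'   `insert`.
#' @export
gen_reads <- function(bundle, config = sim_config(), sample_id = "S1") {
  stopifnot(inherits(bundle, "reference_bundle"),
            inherits(config, "sim_config"))
  n <- config$n_reads
  out <- data.frame(id = character(0), sequence = character(0),
                    stringsAsFactors = FALSE)
  if (n == 0) {
    rs <- read_set(out)
    rs$truth_class <- character(0)
    return(rs)
  }
  set.seed(config$seed)
  kingdom <- ifelse(runif(n) < config$plant_frac, "plant", "animal")
  is_frag <- runif(n) < config$degradation_fraction
  shifts <- function(k) {
    a <- as.integer(names(config$shift_probs))
    mag <- sample(a, k, replace = TRUE, prob = config$shift_probs)
    sgn <- sample(c(-1L, 1L), k, replace = TRUE)
    ifelse(mag == 0L, 0L, mag * sgn)
  }
  mats <- bundle$matures
  insert <- character(n)
  source_id <- character(n)
  s5 <- s3 <- rep(NA_integer_, n)
  for (kg in c("plant", "animal")) {
    # miRNA-derived reads
    sel <- which(kingdom == kg & !is_frag)
    if (length(sel)) {
      mk <- mats[mats$kingdom == kg, ]
      w <- rep(1, nrow(mk))
      if (!is.null(config$mirna_abundance)) {
        hit <- match(mk$mature_id, names(config$mirna_abundance))
        w[!is.na(hit)] <- config$mirna_abundance[hit[!is.na(hit)]]
      }
      pick <- sample(nrow(mk), length(sel), replace = TRUE, prob = w)
      d5 <- shifts(length(sel)); d3 <- shifts(length(sel))
      for (t in seq_along(sel)) {
        r <- mk[pick[t], ]
        pre <- bundle$precursors[[r$precursor_id]]
        a <- max(1L, r$start + d5[t]); b <- min(nchar(pre), r$end + d3[t])
        s5[sel[t]] <- a - r$start; s3[sel[t]] <- b - r$end
        insert[sel[t]] <- substr(pre, a, b)
        source_id[sel[t]] <- r$mature_id
      }
    }
    # degradation fragments
    sel <- which(kingdom == kg & is_frag)
    if (length(sel)) {
      tx <- if (kg == "plant") bundle$plant_transcripts
            else bundle$animal_transcripts
      pick <- sample(length(tx), length(sel), replace = TRUE)
      fl <- sample(config$fragment_length_range[1]:
                     config$fragment_length_range[2],
                   length(sel), replace = TRUE)
      st <- floor(runif(length(sel)) *
                    (nchar(tx)[pick] - fl + 1)) + 1L
      insert[sel] <- substr(tx[pick], st, st + fl - 1L)
      source_id[sel] <- names(tx)[pick]
    }
  }
  raw <- substr(paste0(as_dna(insert), config$adapter),
                1L, config$read_length)
  rs <- read_set(data.frame(
    id = sprintf("%s_read%06d", sample_id, seq_len(n)),
    sequence = raw, stringsAsFactors = FALSE))
  rs$truth_class <- paste0(kingdom, ifelse(is_frag, "_fragment", "_miRNA"))
  rs$truth_source <- source_id
  rs$shift5 <- s5
  rs$shift3 <- s3
  rs$insert <- as_dna(insert)
  rs
}

#' Paper-scale phenotype effect specifications
#'
#' Returns the effect sizes of the feeding experiments as configuration:
#' trait, control mean/SD (from the bundled synthetic control fixture) and
#' the treatment effect (percent for weight/length/eggs, absolute for
#' developmental time and ovariole count).
#'
#' @param treatment one of "pollen_rna", "mirna_pool", "mir162a".
#' @return data frame with columns `trait`, `control_mean`, `control_sd`,
#'   `effect`, `effect_type`.
#' @export
honeybee_effect_specs <- function(treatment = c("pollen_rna", "mirna_pool",
                                                "mir162a")) {
  treatment <- match.arg(treatment)
  ctl <- read.delim(system.file("extdata", "phenotype_controls_synthetic.tsv",
                                package = "pollenmir"),
                    stringsAsFactors = FALSE)
  eff <- read.delim(system.file("extdata", "treatment_effects.tsv",
                                package = "pollenmir"),
                    stringsAsFactors = FALSE)
  eff <- eff[eff$treatment == treatment, c("trait", "effect", "effect_type")]
  merge(ctl, eff, by = "trait")
}

#' Simulate an individual-level phenotype table
#'
#' Control individuals are Normal(control_mean, control_sd) per trait;
#' treated individuals are shifted by the specified effect (percent or
#' absolute).  Count traits (ovarioles, eggs) are rounded and truncated at
#' zero.
#'
#' @param spec data frame as returned by [honeybee_effect_specs()] (columns
#'   `trait`, `control_mean`, `control_sd`, `effect`, `effect_type`).
#' @param n_per_arm individuals per arm (>= 2).
#' @param seed RNG seed.
#' @param arms arm labels; first is the control arm.
#' @return data frame `individual_id`, `arm`, one column per trait.
#' @export
gen_phenotypes <- function(spec, n_per_arm = 30L, seed = 1L,
                           arms = c("control", "treated")) {
  stopifnot(all(c("trait", "control_mean", "control_sd", "effect",
                  "effect_type") %in% names(spec)))
  if (n_per_arm < 2) stop("need at least 2 individuals per arm")
  if (any(spec$control_sd <= 0)) stop("control_sd must be positive")
  if (!all(spec$effect_type %in% c("percent", "absolute")))
    stop("effect_type must be 'percent' or 'absolute'")
  set.seed(seed)
  n_arm <- length(arms)
  out <- data.frame(
    individual_id = sprintf("bee%03d", seq_len(n_per_arm * n_arm)),
    arm = rep(arms, each = n_per_arm), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(spec))) {
    mu <- rep(spec$control_mean[r], n_arm)
    shift <- if (spec$effect_type[r] == "percent")
      spec$control_mean[r] * spec$effect[r] / 100 else spec$effect[r]
    mu[-1] <- mu[-1] + shift
    x <- rnorm(n_per_arm * n_arm, rep(mu, each = n_per_arm),
               spec$control_sd[r])
    if (spec$trait[r] %in% c("ovarioles", "eggs"))
      x <- pmax(0, round(x))
    out[[spec$trait[r]]] <- x
  }
  out
}

#' Simulate a qPCR plate against a log-linear standard curve
#'
#' Ct values follow `intercept + slope * log10(amount) + Normal(0, noise_sd)`.
#' Both the standard dilution series and the unknown samples are emitted.
#'
#' @param curve list or [standard_curve] with `slope` and `intercept`.
#' @param true_amounts positive amounts of the unknowns (one per sample).
#' @param replicates technical replicates per well group.
#' @param noise_sd Ct noise standard deviation.
#' @param seed RNG seed.
#' @param standards amounts of the dilution series.
#' @param gene gene label.
#' @return data frame `well`, `sample`, `gene`, `role` (standard/unknown),
#'   `amount` (NA for unknowns), `ct`.
#' @export
gen_qpcr <- function(curve, true_amounts, replicates = 3L, noise_sd = 0.2,
                     seed = 1L, standards = 10^(0:5), gene = "miR162a") {
  if (any(true_amounts <= 0) || any(standards <= 0))
    stop("amounts must be positive")
  set.seed(seed)
  mk <- function(amounts, role, labels) {
    k <- length(amounts) * replicates
    amt <- rep(amounts, each = replicates)
    data.frame(sample = rep(labels, each = replicates),
               gene = gene, role = role,
               amount = if (role == "standard") amt else NA_real_,
               true_amount = amt,
               ct = curve$intercept + curve$slope * log10(amt) +
                 rnorm(k, 0, noise_sd),
               stringsAsFactors = FALSE)
  }
  std <- mk(standards, "standard", sprintf("std%02d", seq_along(standards)))
  unk <- mk(true_amounts, "unknown",
            sprintf("sample%02d", seq_along(true_amounts)))
  out <- rbind(std, unk)
  out <- cbind(well = sprintf("W%03d", seq_len(nrow(out))), out)
  out
}

#' Simulate a relative-quantification (target vs reference gene) plate
#'
#' Emits per-individual Ct values for a target and a reference gene in a
#' control and a treated arm, with the treated arm's target expression scaled
#' by `true_fold` (fold change on the linear scale, base-2 chemistry).
#'
#' @param true_fold true expression fold change of the target in the treated
#'   arm (e.g. 0.4 for a 60 percent knockdown).
#' @param n_per_arm individuals per arm.
#' @param noise_sd per-well Ct noise SD.
#' @param seed RNG seed.
#' @param base_ct named baseline Ct of target and reference genes.
#' @param target,reference gene labels.
#' @return data frame `sample`, `arm`, `gene`, `ct`.
#' @export
gen_qpcr_relative <- function(true_fold = 0.4, n_per_arm = 6L,
                              noise_sd = 0.15, seed = 1L,
                              base_ct = c(target = 24, reference = 18),
                              target = "amTOR", reference = "amActin") {
  if (true_fold <= 0) stop("true_fold must be positive")
  set.seed(seed)
  arm <- rep(c("control", "treated"), each = n_per_arm)
  sample <- sprintf("ind%02d", seq_len(2L * n_per_arm))
  dct_shift <- ifelse(arm == "treated", -log2(true_fold), 0)
  tgt <- data.frame(sample = sample, arm = arm, gene = target,
                    ct = base_ct[["target"]] + dct_shift +
                      rnorm(2L * n_per_arm, 0, noise_sd),
                    stringsAsFactors = FALSE)
  ref <- data.frame(sample = sample, arm = arm, gene = reference,
                    ct = base_ct[["reference"]] +
                      rnorm(2L * n_per_arm, 0, noise_sd),
                    stringsAsFactors = FALSE)
  rbind(tgt, ref)
}

#' Write a reference bundle to standard formats
#'
#' FASTA for transcripts, precursors and mRNAs; a mature-coordinate TSV
#' (`precursor_id`, `mature_id`, `start`, `end`, `kingdom`; 1-based
#' inclusive).
#'
#' @param bundle a [reference_bundle()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plant = file.path(dir, "plant_transcripts.fa"),
             animal = file.path(dir, "animal_transcripts.fa"),
             precursors = file.path(dir, "precursors.fa"),
             matures = file.path(dir, "matures.tsv"),
             mrnas = file.path(dir, "mrnas.fa"))
  write_fasta(bundle$plant_transcripts, paths["plant"])
  write_fasta(bundle$animal_transcripts, paths["animal"])
  write_fasta(bundle$precursors, paths["precursors"])
  write.table(bundle$matures, paths["matures"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(bundle$mrnas)) write_fasta(bundle$mrnas, paths["mrnas"])
  invisible(paths)
}

#' Synthetic ortholog map and GO annotation tables
#'
#' Builds a bee-to-fly ortholog table and fly GO annotations in which a
#' configurable share of the terms covering the supplied target genes are
#' development-related by construction, so enrichment behaviour can be
#' tested against known truth.
#'
#' @param bee_genes character vector of bee gene ids (the background).
#' @param target_genes subset of `bee_genes` that the development terms
#'   preferentially annotate.
#' @param n_terms total GO terms.
#' @param n_dev_terms how many terms are development-related and enriched in
#'   the targets.
#' @param seed RNG seed.
#' @return list with `orthologs` (bee_gene_id, fly_gene_id) and
#'   `annotations` (gene_id, go_id, go_name) data frames.
#' @export
gen_annotations <- function(bee_genes, target_genes, n_terms = 10L,
                            n_dev_terms = 6L, seed = 1L) {
  stopifnot(all(target_genes %in% bee_genes), n_dev_terms <= n_terms)
  set.seed(seed)
  fly <- sprintf("FBgn%07d", seq_along(bee_genes))
  orth <- data.frame(bee_gene_id = bee_genes, fly_gene_id = fly,
                     stringsAsFactors = FALSE)
  fly_targets <- fly[match(target_genes, bee_genes)]
  dev_names <- c("imaginal disc development", "ovarian follicle development",
                 "larval development", "metamorphosis",
                 "body morphogenesis", "oogenesis",
                 "wing disc development", "growth regulation")
  other_names <- c("cuticle pigmentation", "phototransduction",
                   "ion transport", "chitin metabolism", "muscle contraction",
                   "circadian rhythm", "odorant binding")
  nm <- c(dev_names[seq_len(n_dev_terms)],
          other_names[seq_len(n_terms - n_dev_terms)])
  ann <- do.call(rbind, lapply(seq_len(n_terms), function(t) {
    dev <- t <= n_dev_terms
    # development terms concentrate on targets; others are uniform
    in_t <- if (dev)
      unique(c(sample(fly_targets,
                      min(length(fly_targets),
                          max(1, ceiling(0.6 * length(fly_targets))))),
               sample(fly, min(3, length(fly)))))
    else sample(fly, max(3, stats::rbinom(1, length(fly), 0.15)))
    data.frame(gene_id = in_t, go_id = sprintf("GO:%07d", 8000 + t),
               go_name = nm[t], stringsAsFactors = FALSE)
  }))
  list(orthologs = orth, annotations = ann)
}
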