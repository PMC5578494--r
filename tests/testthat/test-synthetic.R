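test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 5, n_reads = 400)
  b1 <- gen_references(cfg); b2 <- gen_references(cfg)
  expect_identical(b1, b2)
  r1 <- gen_reads(b1, cfg); r2 <- gen_reads(b2, cfg)
  expect_identical(r1, r2)
  q1 <- gen_qpcr(list(slope = -3.3, intercept = 38), c(1, 2), seed = 3)
  q2 <- gen_qpcr(list(slope = -3.3, intercept = 38), c(1, 2), seed = 3)
  expect_identical(q1, q2)
})

test_that("reference generator produces the 16-member plant panel", {
  bundle <- gen_references(sim_config(seed = 2), n_plant_mirnas = 16)
  plant <- bundle$matures[bundle$matures$kingdom == "plant", ]
  expect_equal(nrow(plant), 16)
  expect_setequal(plant$mature_id,
                  c("miR156a", "miR157a", "miR158a", "miR160a", "miR162a",
                    "miR166a", "miR166g", "miR167a", "miR168a", "miR172a",
                    "miR172c", "miR390a", "miR397a", "miR403", "miR824",
                    "miR845a"))
  # canonical miR162a mature is embedded at its annotated coordinates
  expect_equal(mature_seq(bundle, "miR162a"), mir162a_sequence())
})

test_that("mature coordinates outside the precursor are rejected", {
  expect_error(
    reference_bundle(
      plant_transcripts = c(t1 = "ACGUACGUACGU"),
      animal_transcripts = c(t2 = "ACGUACGUACGU"),
      precursors = c(p1 = paste(rep("ACGUA", 5), collapse = "")),  # 25 nt
      matures = data.frame(precursor_id = "p1", mature_id = "m1",
                           start = 10L, end = 30L, kingdom = "plant")),
    "outside its precursor")
  expect_error(sim_config(fragment_length_range = c(5, 40)), "within")
  expect_error(sim_config(kingdom_mix = c(plant = 1.4)), "fraction")
  expect_error(gen_phenotypes(
    data.frame(trait = "weight", control_mean = 100, control_sd = -1,
               effect = 0, effect_type = "percent"), 10, 1),
    "positive")
})

test_that("read truth counts follow configured abundance (binomial check)", {
  cfg <- sim_config(seed = 11, n_reads = 10000,
                    kingdom_mix = c(plant = 1),
                    degradation_fraction = 0.2,
                    mirna_abundance = c(miR162a = 0.5))
  # remaining 15 plant matures share weight 1 each; p(miR162a | miRNA read)
  bundle <- gen_references(cfg)
  reads <- gen_reads(bundle, cfg)
  mir_reads <- reads[reads$truth_class == "plant_miRNA", ]
  # weights: miR162a 0.5 vs 15 x 1 -> p = 0.5/15.5
  p <- 0.5 / 15.5
  n <- nrow(mir_reads)
  obs <- sum(mir_reads$truth_source == "miR162a")
  expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)))
  # and the miRNA/degradation split matches the configured fraction
  expect_lt(abs(sum(reads$truth_class == "plant_fragment") - 10000 * 0.2),
            3 * sqrt(10000 * 0.2 * 0.8))
})

test_that("boundary mixtures and degenerate jitter behave exactly", {
  cfg0 <- sim_config(seed = 4, n_reads = 600, kingdom_mix = c(plant = 0))
  bundle <- gen_references(cfg0)
  reads <- gen_reads(bundle, cfg0)
  expect_false(any(grepl("^plant", reads$truth_class)))
  # zero reads is an empty set, not an error
  expect_equal(nrow(gen_reads(bundle, sim_config(seed = 1, n_reads = 0))), 0)
  # all-zero jitter: every miRNA insert equals its mature exactly
  cfgz <- sim_config(seed = 4, n_reads = 500,
                     shift_probs = c("0" = 1))
  rz <- gen_reads(bundle, cfgz)
  mz <- rz[rz$truth_class == "animal_miRNA", ]
  mats <- vapply(mz$truth_source, function(id) mature_seq(bundle, id),
                 character(1))
  expect_true(all(as_rna(mz$insert) == as_rna(mats)))
})

test_that("phenotype generator hits configured effects and truncates counts", {
  spec <- data.frame(trait = c("weight", "ovarioles"),
                     control_mean = c(150, 60), control_sd = c(18, 12),
                     effect = c(-14.81, -38),
                     effect_type = c("percent", "absolute"))
  tab <- gen_phenotypes(spec, n_per_arm = 30, seed = 8)
  expect_equal(nrow(tab), 60)
  expect_true(all(tab$ovarioles >= 0))
  expect_true(all(tab$ovarioles == round(tab$ovarioles)))
  # null effects: p-values behave like a null test (no systematic shift)
  null_spec <- transform(spec, effect = 0)
  ps <- vapply(1:100, function(s) {
    compare_groups(gen_phenotypes(null_spec, 15, seed = s), "weight")$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.0)   # sanity: not degenerate
  expect_lt(mean(ps < 0.05), 0.15)  # and near the nominal level
})

test_that("qPCR generator is exactly log-linear at zero noise", {
  curve <- list(slope = -3.3219, intercept = 40)
  plate <- gen_qpcr(curve, true_amounts = c(1, 10), replicates = 2,
                    noise_sd = 0, seed = 1)
  expect_equal(plate$ct,
               curve$intercept + curve$slope * log10(plate$true_amount))
  unk <- plate[plate$role == "unknown", ]
  # amount x10 lowers Ct by exactly one slope unit (perfect efficiency)
  expect_equal(unique(unk$ct[unk$true_amount == 1]) -
                 unique(unk$ct[unk$true_amount == 10]), 3.3219)
  expect_error(gen_qpcr(curve, true_amounts = c(-1, 2)), "positive")
})

test_that("FASTA/FASTQ round trips preserve reads and references", {
  cfg <- sim_config(seed = 9, n_reads = 50)
  bundle <- gen_references(cfg)
  reads <- gen_reads(bundle, cfg)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, as_dna(reads$sequence))
  dir <- tempfile()
  paths <- write_bundle(bundle, dir)
  pre <- read_fasta(paths[["precursors"]])
  expect_equal(unname(pre), unname(bundle$precursors))
})
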