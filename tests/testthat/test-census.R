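test_that("adapter masking clips at the leftmost prefix occurrence", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACG"            # 19 nt
  rs <- read_set(data.frame(
    id = c("full", "none", "short", "noclip"),
    sequence = c(paste0(insert, adapter),     # full adapter
                 insert,                      # no adapter occurrence
                 "ACGTACGTACGT",              # 12 nt, below min_len
                 paste0(insert, "TGGAATT")),  # only 7 nt of adapter
    stringsAsFactors = FALSE))
  out <- mask_and_filter(rs, adapter, min_len = 13, max_len = 28)
  expect_equal(out$id, c("full", "none", "noclip"))
  expect_equal(out$sequence[out$id == "full"], insert)
  expect_equal(out$sequence[out$id == "none"], insert)
  # a 7-nt adapter remnant is below the 8-nt prefix, left in place
  expect_equal(nchar(out$sequence[out$id == "noclip"]), 26)
  # reads containing N are removed as low quality
  rsN <- read_set(data.frame(id = "n", sequence = "ACGTNACGTACGTACGT"))
  expect_equal(nrow(mask_and_filter(rsN, adapter)), 0)
  expect_error(mask_and_filter(rs, ""), "adapter")
  expect_error(mask_and_filter(rs, "ACGT"), "at least 6")
})

test_that("kingdom assignment distinguishes unique, shared and absent reads", {
  shared <- "ACGUACGUACGUACGUACGU"  # 20-mer planted in both kingdoms
  set.seed(31)
  bundle <- reference_bundle(
    plant_transcripts = c(p1 = paste0(random_rna(50), shared,
                                      random_rna(50)),
                          p2 = random_rna(80)),
    animal_transcripts = c(a1 = paste0(random_rna(30), shared,
                                       random_rna(30)),
                           a2 = random_rna(80)),
    precursors = c(pre1 = random_rna(60)),
    matures = data.frame(precursor_id = "pre1", mature_id = "m1",
                         start = 20L, end = 40L, kingdom = "plant"))
  plant_read <- substr(bundle$plant_transcripts[["p2"]], 11, 30)
  rs <- read_set(data.frame(
    id = c("plant", "both", "neither", "allN"),
    sequence = c(plant_read, shared, random_rna(20),
                 strrep("N", 20)), stringsAsFactors = FALSE))
  res <- assign_reads(rs, bundle)
  expect_equal(res$assignments$class,
               c("plant_transcript", "ambiguous", "unassigned",
                 "unassigned"))
  expect_equal(res$assignments$feature_id[1], "p2")
  # brute-force cross-check of the shared 20-mer
  expect_true(grepl(shared, bundle$plant_transcripts[["p1"]], fixed = TRUE) &&
              grepl(shared, bundle$animal_transcripts[["a1"]], fixed = TRUE))
})

test_that("mature matching enforces the two-shift, zero-mismatch rule", {
  bundle <- tiny_bundle()
  ann <- bundle$matures[1, ]
  pre <- bundle$precursors[[ann$precursor_id]]
  for (s5 in -3:3) {
    for (s3 in -3:3) {
      read <- substr(pre, ann$start + s5, ann$end + s3)
      hits <- match_mirna(read, bundle$precursors, bundle$matures,
                          max_shift = 2)
      ok <- abs(s5) <= 2 && abs(s3) <= 2
      expect_equal("miR162a" %in% hits$mature_id, ok,
                   label = sprintf("shift (%d, %d) accepted", s5, s3),
                   expected.label = as.character(ok))
      if (ok) {
        row <- hits[hits$mature_id == "miR162a", ]
        expect_equal(c(row$shift5, row$shift3), c(s5, s3))
      }
    }
  }
  # one internal substitution breaks the exact-substring requirement
  mat <- mature_seq(bundle, "miR162a")
  sub <- mat
  substr(sub, 11, 11) <- if (substr(sub, 11, 11) == "A") "C" else "A"
  expect_equal(nrow(match_mirna(sub, bundle$precursors, bundle$matures)), 0)
})

test_that("census recovers truth labels exactly on zero-jitter libraries", {
  cfg <- sim_config(seed = 21, n_reads = 800, shift_probs = c("0" = 1),
                    degradation_fraction = 0.25)
  bundle <- gen_references(cfg)
  reads <- gen_reads(bundle, cfg)
  cn <- census(reads, bundle)
  truth <- reads[match(cn$assignments$id, reads$id), ]
  is_mir <- grepl("_miRNA$", truth$truth_class)
  expect_true(all(cn$assignments$class[is_mir] == truth$truth_class[is_mir]))
  expect_true(all(cn$assignments$feature_id[is_mir] ==
                    truth$truth_source[is_mir]))
  # fragments never get classified as miRNAs
  expect_false(any(grepl("_miRNA$", cn$assignments$class[!is_mir])))
})

test_that("class counts are conserved through the census", {
  cfg <- sim_config(seed = 13, n_reads = 1200)
  bundle <- gen_references(cfg)
  reads <- gen_reads(bundle, cfg)
  cn <- census(reads, bundle)
  expect_equal(sum(cn$counts$raw_count), cn$n_clean)
  expect_true(all(cn$counts$class %in%
                    c("plant_miRNA", "animal_miRNA", "plant_transcript",
                      "animal_transcript", "ambiguous", "unassigned")))
})

test_that("normalization is exact, idempotent and scale invariant", {
  tab <- data.frame(sample_id = "s", feature_id = c("a", "b"),
                    raw_count = c(200L, 200L))
  out <- normalize_counts(tab)
  expect_equal(out$normalized, c(5e6, 5e6))
  # the cole royal-jelly library size rescales exactly to 1e7
  tab2 <- data.frame(sample_id = "rj", feature_id = sprintf("f%d", 1:5),
                     raw_count = c(9000000L, 500000L, 40000L, 8000L, 986L))
  expect_equal(sum(tab2$raw_count), 9548986L)
  out2 <- normalize_counts(tab2)
  expect_equal(sum(out2$normalized), 1e7)
  # single feature gets the whole library
  expect_equal(normalize_counts(
    data.frame(sample_id = "s", feature_id = "x", raw_count = 3L)
  )$normalized, 1e7)
  # idempotence / scale invariance: pre-scaled raw counts give identical
  # normalized values
  tab3 <- tab2; tab3$raw_count <- tab3$raw_count * 7
  expect_equal(normalize_counts(tab3)$normalized, out2$normalized)
  expect_error(normalize_counts(
    data.frame(sample_id = "s", feature_id = "x", raw_count = 0L)),
    "empty library")
})

test_that("length histogram bins the window and pools the boundaries", {
  rs <- read_set(data.frame(id = sprintf("r%d", 1:4),
                            sequence = c(strrep("A", 21), strrep("C", 21),
                                         strrep("G", 8), strrep("U", 34))))
  h <- length_histogram(rs)
  expect_equal(h$count[h$length == "21"], 2)
  expect_equal(h$count[h$length == "<9"], 1)
  expect_equal(h$count[h$length == ">33"], 1)
  expect_equal(sum(h$count), 4)
  h0 <- length_histogram(rs[0, ])
  expect_true(all(h0$count == 0))
  # a pollen-like library peaks inside the 19-24 nt mature window
  cfg <- sim_config(seed = 17, n_reads = 2000, kingdom_mix = c(plant = 0.9),
                    degradation_fraction = 0.1)
  bundle <- gen_references(cfg)
  cn <- census(gen_reads(bundle, cfg), bundle)
  hh <- cn$histogram[!cn$histogram$pooled, ]
  modal <- as.integer(hh$length[which.max(hh$count)])
  expect_gte(modal, 19); expect_lte(modal, 24)
})
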