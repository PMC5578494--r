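# Shared fixtures, all built in code.

# a tiny hand-made bundle: one plant and one animal precursor with one
# mature each, plus short decoy transcripts
tiny_bundle <- function() {
  plant_pre <- paste0("GAUUACCAGUGGUCAUGAGG",          # 5' flank (20)
                      "UCGAUAAACCUCUGCAUCCAG",          # mature (21..41)
                      "CCAUGGAACGUUAGCCAAUG")           # 3' flank (20)
  animal_pre <- paste0("CGCUAGGAUCCGAAUUCGAA",
                       "UGAGGUAGUAGGUUGUAUAGU",         # mature (21..41)
                       "AAGCUUGGGCUGUAGGCAUC")
  matures <- data.frame(
    precursor_id = c("pre-miR162a", "pre-ame-let-7"),
    mature_id = c("miR162a", "ame-let-7"),
    start = c(21L, 21L), end = c(41L, 41L),
    kingdom = c("plant", "animal"), stringsAsFactors = FALSE)
  set.seed(99)
  reference_bundle(
    plant_transcripts = setNames(random_seq_t(2, 120), c("ptx1", "ptx2")),
    animal_transcripts = setNames(random_seq_t(2, 120), c("atx1", "atx2")),
    precursors = setNames(c(plant_pre, animal_pre),
                          c("pre-miR162a", "pre-ame-let-7")),
    matures = matures,
    mrnas = setNames(random_seq_t(2, 300), c("g1", "g2")))
}

random_seq_t <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

# plant a perfect complementary site for `mirna` into `mrna` at `at`
with_site <- function(mrna, mirna, at) {
  site <- rev_comp(mirna)
  paste0(substr(mrna, 1, at - 1), site,
         substr(mrna, at + nchar(site), nchar(mrna)))
}

random_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                         replace = TRUE), collapse = "")

expect_same_energy <- function(a, b, params) {
  e_dp <- duplex_mfe(a, b, params)$dG
  e_or <- enumerate_structures(a, b, params)
  expect_equal(e_dp, e_or, tolerance = 1e-9,
               label = sprintf("duplex_mfe(%s, %s)", a, b),
               expected.label = "enumeration oracle")
}
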