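---
title: "Methods: models, parameters and design choices in pollenmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in pollenmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenmir)
```

## The scientific problem

Honeybee larvae develop into queens or workers depending on their diet:
royal jelly (a nurse-bee glandular secretion, animal-derived) promotes the
queen fate, while beebread (a pollen-honey mixture, plant-derived) leads to
worker development. Plant pollen carries abundant plant miRNAs; if those
miRNAs survive ingestion they could act as cross-kingdom regulators of bee
genes — most prominently *amTOR*, the target-of-rapamycin gene whose
activity promotes queen development, which carries a candidate binding site
for the plant miRNA miR162a.

`pollenmir` reimplements the computational chain behind this hypothesis as
a reusable, tested package: small-RNA library classification and
normalization, cross-sample miRNA profiling, duplex free-energy target
prediction, GO enrichment of predicted targets, and the qPCR/phenotype
statistics. A synthetic-data generator with hidden truth labels replaces
the sequencing archive, so every stage runs and is testable offline.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `gen_references()` and
`gen_reads()` produce references and libraries with per-read truth labels.

* **Library structure.** A library mixes miRNA-derived reads and
  degradation fragments of tRNA/rRNA/mRNA decoy transcripts. Fragment
  insert lengths span 13–28 nt (the degradation window observed in
  hive-processed samples); mature miRNAs span 19–24 nt, so plant-dominated,
  low-degradation libraries peak inside 19–24 nt, as pollen does.
* **Kingdom mixture.** `kingdom_mix` sets the fraction of reads whose true
  source is a plant sequence; royal-jelly-like libraries use a low value,
  beebread/pollen-like libraries a high one.
* **Terminus jitter.** Sequenced miRNA reads rarely match annotated mature
  coordinates exactly. Each terminus of a miRNA read is shifted by a draw
  from `shift_probs` (default mass 0.70/0.20/0.08/0.02 on |shift| =
  0/1/2/3). The default deliberately places mass at |shift| = 3 so that the
  matching rule's rejection region contains true events — tests can verify
  both acceptance and rejection.
* **Alphabet.** Reads are emitted in DNA (T) with a 3' adapter appended and
  truncation at the 36-cycle read length, as a sequencer reports them; all
  comparisons normalize U/T internally.
* **Panel.** The 16 plant matures use the panel names observed at highest
  abundance in beebread and pollen (miR156a … miR845a); miR162a carries its
  canonical 21-nt mature sequence, the others are simulated. This keeps the
  worked example (miR162a vs its target site) anchored to a real sequence
  while everything else is synthetic.

What the generator does **not** emulate: sequencing errors beyond adapter
truncation, quality-score variation, multi-mapping across paralogous
precursor families, and the heavy-tailed length artefacts of real degradome
data. Passing tests therefore demonstrate correctness of the *computational
chain*, not performance on real libraries.

## The census

`census()` runs masking → miRNA matching → transcript assignment →
normalization.

* **Adapter masking** clips at the leftmost exact occurrence of the first
  8 nt of the adapter (the full adapter if shorter). Reads containing N are
  treated as low quality and removed; insert lengths outside 13–28 nt are
  filtered.
* **Transcript assignment** is exact sense-strand substring matching
  against each kingdom's transcripts. At desk scale an indexed aligner
  would be over-engineering; one C-level fixed-string search over a
  concatenated reference gives identical results.
* **miRNA matching** requires the read to be an exact, gap-free substring
  of a precursor (the zero-mismatch, zero-gap optimum of a local alignment
  with match +1, mismatch −3, gap −5 reduces to exactly this), with each
  terminus within `max_shift` (default 2) nt of an annotated mature
  terminus. "Two shifts" is read as *per-terminus* deviation — the
  strictest common interpretation — and is configurable.
* **One class per read.** miRNA hits take precedence over transcript hits;
  hits in both kingdoms are `ambiguous` rather than double-counted, so
  class counts always sum to the number of clean reads. A read matching
  several matures in one kingdom counts once, attributed to the mature with
  the smallest total terminus shift (ties broken lexicographically).
* **Normalization** scales each library to 10,000,000 reads, keeping
  fractional values so the per-sample sum is exact.

## Profile comparison

Detection of a miRNA type uses a raw-count threshold of 1 read
(configurable — no published threshold exists). Pearson correlation between
profiles is computed on log10(x+1)-transformed normalized counts over the
union of ids (the transform is configurable; the log tames the
orders-of-magnitude abundance range). The representative panel ranks
matures by mean normalized abundance across the beebread and pollen
profiles, with deterministic id tie-breaks, so the selected panel is always
a prefix of the full ranking.

## Hybrid thermodynamics

`duplex_mfe()` computes the minimum-free-energy *intermolecular* duplex
under a nearest-neighbor model:

* allowed pairs AU, UA, CG, GC, GU, UG;
* stacked helices scored by doublet ΔG°37 from a bundled Turner-2004-style
  plain-text table (`inst/extdata/nn_dg37.tsv`, swappable);
* bulges and interior loops up to 15 unpaired nt per strand, with
  length-dependent initiation penalties and a capped asymmetry term;
* duplex initiation +4.09 kcal/mol; terminal AU/GU penalty 0.45 kcal/mol at
  both duplex ends; no dangling-end terms; no intramolecular structure.

A finite-energy structure must contain at least two stacked pairs —
isolated single pairs are physically meaningless and are reported as the
+Inf sentinel. The dynamic program tracks a "contains a stack" flag, which
keeps the recursion exact under this constraint, and its traceback prefers
stacks over loops and smaller over larger loops on energy ties.

Correctness is established two ways: a brute-force enumerator
(`enumerate_structures()`, independent of the DP) must agree exactly on
hundreds of random short pairs, and every reported structure must re-score
to its reported energy from the parameter table. An additional test
cross-checks absolute scale against an independent thermodynamics
implementation (ViennaRNA's RNAduplex) within 2 kcal/mol on perfect
helices — agreement there is expected only approximately, because dangles
and coaxial terms differ.

`scan_sites()` slides a window of `miRNA length + max_loop` along an mRNA,
reports merged non-overlapping sites with dG at or below the −17 kcal/mol
cutoff used for genuine miRNA-target pairs, and requires seed pairing:
miRNA positions 2–7 contiguously paired, G:U allowed (functional plant
miRNA sites in animal transcripts are observed with a seed wobble, so a
strict Watson-Crick seed would be wrong here). Windows that cannot host a
contiguous seed helix are pruned with a character-class search before the
dynamic program runs; this is a pure speed-up and cannot change results,
because a reportable site must have the seed paired anyway.

### The worked example

The packaged miR162a/target-site example uses a **synthetic stand-in
site** (`inst/extdata/amtor_site_synthetic.fa`, labelled synthetic): the
reverse complement of miR162a with a single G:U wobble in the seed helix
and a central 2×2 internal loop. That construction encodes the qualitative
character reported for the real site — near-perfect complementarity with a
seed wobble — without copying a transcript sequence. Under the bundled
table its hybrid energy is about −26 kcal/mol, well below the −17 kcal/mol
site-calling cutoff, on the scale reported for the genuine miR162a–amTOR
hybrid. Users with the real amTOR mRNA can substitute it directly:
`scan_sites(mir162a_sequence(), amtor_mrna)`.

## The dual-predictor target screen

`complementarity_score()` is a weighted-complementarity local alignment in
the style of miRanda: Watson-Crick +5, G:U +1, mismatch −3, affine gaps
(−9/−4), all substitution scores doubled at miRNA positions 2–8. The
default reporting threshold of 140 equals the perfect-match score of a
21-mer, so shorter matures cannot reach it — deliberate: short perfect
matches are weaker evidence. `predict_targets()` calls a gene a target
only when an energy site and a score site overlap by at least 1 nt
("both predictors at the same locus"). Published target lists from the
original tool binaries are *not* a reproduction goal — they depend on tool
versions and on a specific transcriptome build; the planted-truth tests
define correctness instead.

`mutate_seed()` substitutes the site bases pairing the first `n_mut` miRNA
seed positions with bases that can form neither a Watson-Crick nor a wobble
pair, the computational analogue of a mutant-binding-site reporter
construct; re-scanning the mutated site yields no prediction.

## GO enrichment

Per term, a 2×2 Pearson chi-square (no continuity correction, 1 df)
compares the in-term proportion among targets with the rest of the
background. The enrichment *decision* applies no multiple-testing
correction — matching the stated p < 0.05 criterion of the analysis being
reproduced — but a Benjamini-Hochberg column is always emitted alongside.
The background defaults to all annotated genes; GO-graph propagation is not
performed (annotations are taken as given). Terms with a zero expected
cell are skipped and logged rather than producing unstable statistics.

## Quantitative layer

* **Standard curves** are least-squares fits of Ct on log10(amount);
  efficiency is 10^(−1/slope) − 1. Absolute quantification inverts the
  curve and divides by either normalization denominator (µg total RNA or g
  sample mass).
* **ΔΔCt** relative quantification assumes base-2 chemistry:
  fold = 2^−((Ct_target − Ct_ref) − mean control ΔCt). The control arm's
  *geometric* mean fold is 1 by construction.
* **Phenotypes**: two arms use the two-sided Student's t-test with pooled
  variance (Welch available by flag), three or more use one-way ANOVA with
  no post-hoc tests. Percent effects are computed on raw means relative to
  the control arm. Count traits (ovarioles, eggs) are rounded and
  truncated at zero by the generator; with a control mean of 60 and SD 12,
  truncation biases a −38 ovariole effect by under 0.2 ovarioles, which the
  recovery tests account for explicitly.

The default effect sizes shipped with the package
(`honeybee_effect_specs()`) are the reported feeding-experiment effects:
total pollen RNA (+0.49 d development, −14.81 % weight, −6.55 % length,
−21 ovarioles), the 16-miRNA synthetic pool (+0.58 d, −10.27 %, −4.01 %,
−38 ovarioles) and miR162a alone (+0.17 d, −7.87 %, −4.49 %, −29
ovarioles). Control means and SDs (`phenotype_controls_synthetic.tsv`) are
synthetic but realistic for laboratory-reared bees, which develop
intermediate worker-queen characters: weight 150 ± 18 mg, length
13 ± 0.8 mm, development 19.5 ± 1 d, ovarioles 60 ± 12 (inside the 30–80
range such bees show), and n = 30 per arm, at the upper end of the 25–30
per-arm sizes typical of these experiments.

## Bundled flowering-stage tables

`inst/extdata/{cole,camellia}_flowering_counts_synthetic.tsv` are
*synthetic* per-sample miRNA count tables, generated by
`sim_supp_tables()`, that carry the structure of the two deep-sequenced
flowering stages: per-sample detected plant miRNA types of 41/71/58/53 and
bee types of 46/39/14/15 (royal jelly / honey / beebread / pollen) in the
cole-like stage; a shared long-tailed abundance spectrum that makes
beebread and pollen correlate near 1 while royal jelly does not; and a
camellia-like beebread in which exactly 13 of the 16-member panel are
detectable. They exercise the detection/panel/overlap set algebra on
inputs with the published summary structure; they are not the deposited
tables.

## Problem sizes and numerical choices

Defaults are chosen so the whole chain runs comfortably on one CPU:
simulated libraries of a few thousand reads, mRNAs under 1 kb, 200-replicate
phenotype recoveries, 200-pair oracle sweeps. Energies are compared at
1e-9 kcal/mol; normalization keeps fractional counts so per-sample sums are
exact; ties everywhere break deterministically (smallest shift, then
lexicographic id; stacks before loops). Degenerate inputs fail loudly:
empty libraries, all-zero samples, zero-variance profiles, curves with
fewer than three distinct standards, single-arm phenotype tables.

## Known limitations

* No intramolecular structure, partition function, site accessibility or
  temperature dependence beyond the 37 °C tables in the duplex model.
* The nearest-neighbor table is Turner-2004-style but bundled from a
  package-local file; absolute energies carry table provenance uncertainty
  of order 1 kcal/mol (relative comparisons are unaffected).
* Exact substring matching cannot model SNPs or sequencing errors in
  reads; that is faithful to a perfect-match census, not a limitation of
  the tests.
* GO annotations are used as given: no ontology propagation, no
  evidence-code filtering.
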