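# Dual-predictor target calling: the energy scan (scan_sites) intersected
# with a weighted-complementarity local alignment, plus seed mutagenesis.

#' Weighted-complementarity alignment parameters
#'
#' Defaults mirror the published miRanda scheme: Watson-Crick pair +5,
#' G:U wobble +1, mismatch -3, affine gaps (-9 open, -4 extend), with all
#' substitution scores doubled at miRNA seed positions 2-8.
#'
#' @param match,wobble,mismatch substitution weights.
#' @param gap_open,gap_extend affine gap weights (both negative).
#' @param seed_positions miRNA positions whose scores are scaled.
#' @param seed_scale multiplier applied at seed positions.
#' @param threshold minimal reportable score (140 = the perfect-match score
#'   of a 21-mer under the defaults).
#' @return list of class `miranda_params`.
#' @export
miranda_params <- function(match = 5, wobble = 1, mismatch = -3,
                           gap_open = -9, gap_extend = -4,
                           seed_positions = 2:8, seed_scale = 2,
                           threshold = 140) {
  stopifnot(gap_open < 0, gap_extend < 0, match > 0)
  structure(list(match = match, wobble = wobble, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_positions = as.integer(seed_positions),
                 seed_scale = seed_scale, threshold = threshold),
            class = "miranda_params")
}

#' Local antiparallel complementarity score
#'
#' Maximal-scoring local alignment between a miRNA and a site read
#' antiparallel (the site is reversed internally), scoring complementarity
#' rather than identity.  A completely non-complementary pair scores 0
#' (empty alignment); the score is invariant to non-complementary flanking
#' context.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param site site or mRNA sequence 5'->3'.
#' @param params a [miranda_params()].
#' @return list of class `complementarity_score`: `score`, `pairs` (matrix of
#'   aligned (mirna_pos, site_pos), 1-based from each 5' end), `site_start`,
#'   `site_end` (site coordinates of the alignment).
#' @export
complementarity_score <- function(mirna, site, params = miranda_params()) {
  if (!nzchar(mirna) || !nzchar(site)) stop("sequences must be non-empty")
  check_rna(mirna, "miRNA")
  check_rna(site, "site")
  L <- nchar(site)
  rsite <- paste(rev(strsplit(as_rna(site), "")[[1]]), collapse = "")
  res <- .sw_complement_cpp(base_codes(mirna), base_codes(rsite),
                            params$match, params$wobble, params$mismatch,
                            params$gap_open, params$gap_extend,
                            params$seed_positions, params$seed_scale)
  pairs <- res$pairs
  if (nrow(pairs)) pairs[, 2] <- L - pairs[, 2] + 1L  # back to site coords
  colnames(pairs) <- c("mirna_pos", "site_pos")
  structure(list(score = res$score, pairs = pairs,
                 site_start = if (res$score > 0) L - res$r_range[2] + 1L
                              else NA_integer_,
                 site_end = if (res$score > 0) L - res$r_range[1] + 1L
                            else NA_integer_),
            class = "complementarity_score")
}

score_sites <- function(mirna, mrna, params = miranda_params(),
                        max_sites = 10L) {
  # iterative best-local-alignment extraction: report, mask, repeat
  out <- list()
  seq <- as_rna(mrna)
  for (k in seq_len(max_sites)) {
    cs <- complementarity_score(mirna, seq, params)
    if (cs$score < params$threshold) break
    out[[k]] <- data.frame(site_start = cs$site_start,
                           site_end = cs$site_end, score = cs$score)
    substr(seq, cs$site_start, cs$site_end) <-
      strrep("N", cs$site_end - cs$site_start + 1L)
  }
  if (!length(out))
    return(data.frame(site_start = integer(0), site_end = integer(0),
                      score = numeric(0)))
  do.call(rbind, out)
}

#' Dual-predictor target prediction
#'
#' A gene is called a target of a miRNA when at least one energy site
#' ([scan_sites()], dG cutoff and seed pairing) overlaps (>= 1 nt) a
#' complementarity site scoring at or above the threshold.  The number of
#' distinct panel miRNAs hitting each gene is reported.
#'
#' @param panel named character vector of miRNA sequences (5'->3').
#' @param mrnas named character vector of mRNA sequences.
#' @param energy_params an [nn_params()] table.
#' @param score_params a [miranda_params()].
#' @param seed a [seed_spec()].
#' @param cutoff energy cutoff in kcal/mol (default -17).
#' @return data frame of class `target_predictions`: `gene_id`, `mirna_id`,
#'   `site_start`, `site_end`, `dG`, `score`, `n_mirnas_per_gene`.
#' @export
predict_targets <- function(panel, mrnas, energy_params = nn_params(),
                            score_params = miranda_params(),
                            seed = seed_spec(), cutoff = -17) {
  stopifnot(length(names(panel)) == length(panel),
            length(names(mrnas)) == length(mrnas))
  rows <- list()
  for (g in names(mrnas)) {
    for (m in names(panel)) {
      es <- scan_sites(panel[[m]], mrnas[[g]], energy_params, seed, cutoff)
      if (!nrow(es)) next
      ss <- score_sites(panel[[m]], mrnas[[g]], score_params)
      if (!nrow(ss)) next
      for (r in seq_len(nrow(es))) {
        ov <- ss$site_start <= es$site_end[r] & es$site_start[r] <= ss$site_end
        if (any(ov))
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, mirna_id = m,
            site_start = es$site_start[r], site_end = es$site_end[r],
            dG = es$dG[r], score = max(ss$score[ov]),
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene_id = character(0), mirna_id = character(0),
                  site_start = integer(0), site_end = integer(0),
                  dG = numeric(0), score = numeric(0),
                  stringsAsFactors = FALSE)
  nm <- tapply(out$mirna_id, out$gene_id, function(x) length(unique(x)))
  out$n_mirnas_per_gene <- if (nrow(out)) as.integer(nm[out$gene_id])
                           else integer(0)
  class(out) <- c("target_predictions", "data.frame")
  out
}

#' Disrupt the seed-pairing positions of a predicted site
#'
#' Substitutes the site bases that pair the miRNA seed with bases that can
#' form neither a Watson-Crick nor a G:U pair with the corresponding miRNA
#' base, abolishing the prediction at that locus (the computational analogue
#' of a mutant-binding-site reporter).
#'
#' @param site site sequence 5'->3'.
#' @param duplex a `duplex_result` for (miRNA, site) with `seed_paired`
#'   TRUE.
#' @param n_mut number of seed-pairing site positions to substitute
#'   (default 3, taken from the 5'-most miRNA seed positions).
#' @param seed the [seed_spec()] that defined the seed.
#' @return the mutated site sequence (same alphabet case as RNA).
#' @export
mutate_seed <- function(site, duplex, n_mut = 3L, seed = seed_spec()) {
  if (!isTRUE(duplex$seed_paired))
    stop("duplex does not have the seed paired; nothing to mutate")
  if (n_mut == 0) return(as_rna(site))
  # a partner that pairs with nothing: A and C can never pair with purines'
  # partners; pick per miRNA base a base that is neither WC nor wobble
  non_partner <- c(A = "C", C = "A", G = "A", U = "C")
  s <- strsplit(as_rna(site), "")[[1]]
  m <- strsplit(duplex$mirna, "")[[1]]
  sp <- seed$positions[seq_len(min(n_mut, length(seed$positions)))]
  idx <- match(sp, duplex$pairs[, "mirna_pos"])
  tgt <- duplex$pairs[idx, "site_pos"]
  s[tgt] <- non_partner[m[sp]]
  paste(s, collapse = "")
}
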