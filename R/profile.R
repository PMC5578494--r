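# Cross-sample miRNA profile comparison: type detection, Pearson
# correlation, representative-panel selection and set overlap.

#' Build per-sample miRNA profiles from census results
#'
#' @param censuses list of `srna_census` objects (or a single one).
#' @param kingdom "plant" or "animal" miRNA class to extract.
#' @return named list of profiles; each profile is a data frame
#'   (`mature_id`, `raw`, `normalized`) with attributes `sample_id` and
#'   `kingdom`.
#' @export
mirna_profiles <- function(censuses, kingdom = "plant") {
  if (inherits(censuses, "srna_census")) censuses <- list(censuses)
  cls <- paste0(kingdom, "_miRNA")
  out <- lapply(censuses, function(cn) {
    rows <- cn$counts[cn$counts$class == cls, , drop = FALSE]
    p <- data.frame(mature_id = rows$feature_id, raw = rows$raw_count,
                    normalized = rows$normalized, stringsAsFactors = FALSE)
    attr(p, "sample_id") <- cn$sample_id
    attr(p, "kingdom") <- kingdom
    p
  })
  names(out) <- vapply(censuses, function(cn) cn$sample_id, character(1))
  out
}

#' Detected miRNA types in a profile
#'
#' @param profile a profile data frame (`mature_id`, `raw`).
#' @param min_reads detection threshold on the raw count (default 1).
#' @return character vector of detected mature ids.
#' @export
detect_types <- function(profile, min_reads = 1) {
  sort(unique(profile$mature_id[profile$raw >= min_reads]))
}

#' Pearson correlation between two miRNA profiles
#'
#' Profiles are aligned on the union of their mature ids (absent = 0) and
#' transformed before correlating.
#'
#' @param a,b profile data frames (`mature_id`, `normalized`).
#' @param transform "log10p1" (log10(x + 1), default) or "identity".
#' @return Pearson r in [-1, 1].
#' @export
correlate_profiles <- function(a, b, transform = c("log10p1", "identity")) {
  transform <- match.arg(transform)
  ids <- sort(union(a$mature_id, b$mature_id))
  va <- setNames(rep(0, length(ids)), ids)
  vb <- va
  va[a$mature_id] <- a$normalized
  vb[b$mature_id] <- b$normalized
  if (transform == "log10p1") {
    va <- log10(va + 1); vb <- log10(vb + 1)
  }
  if (var(va) == 0 || var(vb) == 0)
    stop("correlation undefined: a profile has zero variance")
  cor(va, vb, method = "pearson")
}

#' Select the representative high-abundance panel
#'
#' Ranks plant matures by their mean normalized abundance across the
#' beebread and pollen profiles and returns the top `k` (ties broken by
#' mature id; the returned panel is always a prefix of the full ranking).
#'
#' @param profiles list of profile data frames (typically beebread and
#'   pollen).
#' @param k panel size (default 16).
#' @return object of class `panel_selection`: list with `panel` (ordered
#'   ids), `k`, `ranking` (full ranked data frame) and `criterion`.
#' @export
select_representative <- function(profiles, k = 16L) {
  if (inherits(profiles, "data.frame")) profiles <- list(profiles)
  ids <- sort(unique(unlist(lapply(profiles, `[[`, "mature_id"))))
  mat <- vapply(profiles, function(p) {
    v <- setNames(rep(0, length(ids)), ids)
    v[p$mature_id] <- p$normalized
    v
  }, numeric(length(ids)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(ids))
  mean_ab <- rowMeans(mat)
  ord <- order(-mean_ab, ids)
  ranking <- data.frame(mature_id = ids[ord], mean_normalized = mean_ab[ord],
                        stringsAsFactors = FALSE)
  k_eff <- min(as.integer(k), nrow(ranking))
  structure(list(panel = ranking$mature_id[seq_len(k_eff)], k = k_eff,
                 ranking = ranking,
                 criterion = "mean normalized abundance across samples"),
            class = "panel_selection")
}

#' Set overlap (Venn counts)
#'
#' @param a,b character vectors (coerced to sets).
#' @return named integer vector: `both`, `only_a`, `only_b`.
#' @export
overlap_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  c(both = length(intersect(a, b)),
    only_a = length(setdiff(a, b)),
    only_b = length(setdiff(b, a)))
}

#' Read a per-sample miRNA count table (supplementary-table layout)
#'
#' Expects a TSV with columns `mature_id`, `kingdom`, then one raw-count
#' column per sample.  Returns one profile per sample; normalized values are
#' computed with [normalize_counts()] over all rows of that sample.
#'
#' @param path TSV path.
#' @param total normalization target (default 1e7).
#' @return named list of profile data frames.
#' @export
read_supp_counts <- function(path, total = 1e7) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("mature_id", "kingdom") %in% names(tab)))
  samples <- setdiff(names(tab), c("mature_id", "kingdom"))
  out <- lapply(samples, function(sm) {
    long <- data.frame(sample_id = sm, feature_id = tab$mature_id,
                       raw_count = tab[[sm]], stringsAsFactors = FALSE)
    long <- normalize_counts(long, total)
    p <- data.frame(mature_id = long$feature_id, raw = long$raw_count,
                    normalized = long$normalized,
                    kingdom = tab$kingdom, stringsAsFactors = FALSE)
    attr(p, "sample_id") <- sm
    p
  })
  names(out) <- samples
  out
}

plant_only <- function(profile) {
  if (!"kingdom" %in% names(profile)) return(profile)
  p <- profile[profile$kingdom == "plant", , drop = FALSE]
  attr(p, "sample_id") <- attr(profile, "sample_id")
  p
}

#' Simulate supplementary-table-style per-sample count tables
#'
#' Generates two flowering-stage tables (cole-like and camellia-like) with
#' the study system's structure: four samples (royal jelly, honey, beebread,
#' pollen), per-sample detected plant miRNA type counts of 41/71/58/53 and
#' bee type counts of 46/39/14/15 in the first stage, plant miRNAs far more
#' abundant in beebread/pollen, bee miRNAs in royal jelly, and exactly 13 of
#' the 16-member representative panel detectable in the second stage's
#' beebread.  Used to build the bundled synthetic fixtures.
#'
#' @param seed RNG seed.
#' @return list of two data frames (`cole`, `camellia`) in the layout read
#'   by [read_supp_counts()].
#' @export
sim_supp_tables <- function(seed = 20170831) {
  set.seed(seed %% .Machine$integer.max)
  plant_ids <- unique(c(PLANT_PANEL,
                        sprintf("miR%d%s", rep(c(159, 164, 169, 171, 393,
                                                 394, 396, 398, 408, 827,
                                                 858, 2111), each = 6),
                                letters[1:6])))
  plant_ids <- plant_ids[1:80]
  bee_ids <- sprintf("ame-miR-%d", sort(sample(1:3000, 60)))
  mk_table <- function(types_plant, types_bee, panel_in_beebread) {
    samples <- c("royal_jelly", "honey", "beebread", "pollen")
    tab <- data.frame(mature_id = c(plant_ids, bee_ids),
                      kingdom = rep(c("plant", "animal"),
                                    c(length(plant_ids), length(bee_ids))),
                      stringsAsFactors = FALSE)
    # beebread and pollen share one long-tailed plant-miRNA abundance
    # profile (their compositions are near-identical); Poisson noise sits on
    # top of it, and detection follows abundance so only rare types are
    # discordant between the two
    lam_shared <- setNames(stats::rlnorm(length(plant_ids), 3, 1.5),
                           plant_ids)
    lam_shared[panel_in_beebread] <- lam_shared[panel_in_beebread] + 7000
    others_by_rank <- names(sort(lam_shared[setdiff(plant_ids,
                                                    panel_in_beebread)],
                                 decreasing = TRUE))
    for (si in seq_along(samples)) {
      sm <- samples[si]
      np <- types_plant[si]; nb <- types_bee[si]
      det_p <- if (sm %in% c("beebread", "pollen"))
        c(panel_in_beebread,
          others_by_rank[seq_len(np - length(panel_in_beebread))])
      else sample(plant_ids, np)
      det_b <- sample(bee_ids, nb)
      x <- integer(nrow(tab))
      ip <- tab$mature_id %in% det_p
      # plant miRNAs: high abundance in beebread/pollen, low in royal jelly
      x[ip] <- if (sm %in% c("beebread", "pollen"))
        1L + stats::rpois(sum(ip), lam_shared[tab$mature_id[ip]])
      else 1L + stats::rpois(sum(ip), 12 * stats::rbeta(sum(ip), 1, 3))
      hi_b <- if (sm == "royal_jelly") 800 else 6
      ib <- tab$mature_id %in% det_b
      x[ib] <- 1L + stats::rpois(sum(ib), hi_b * stats::rbeta(sum(ib), 1, 3))
      tab[[sm]] <- x
    }
    tab
  }
  cole <- mk_table(c(41, 71, 58, 53), c(46, 39, 14, 15), PLANT_PANEL)
  panel13 <- c(sort(sample(PLANT_PANEL, 13)))
  camellia <- mk_table(c(38, 64, 55, 49), c(41, 35, 12, 13), panel13)
  # camellia beebread/pollen must not detect the 3 dropped panel members
  drop3 <- setdiff(PLANT_PANEL, panel13)
  camellia[camellia$mature_id %in% drop3,
           c("royal_jelly", "honey", "beebread", "pollen")] <- 0L
  list(cole = cole, camellia = camellia)
}
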