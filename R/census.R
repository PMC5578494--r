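# Small-RNA read census: adapter masking, length/quality filtering, exact
# dual-kingdom transcript assignment, miRBase-style mature matching with a
# terminus shift rule, and library-size normalization.

# Exact-substring index: reference sequences concatenated (lexicographic id
# order) with a '#' separator, so one C-level fixed-string search covers the
# whole reference set.  Reads are ACGUN-only and can never span a separator.
seq_index <- function(seqs) {
  if (!length(seqs)) return(NULL)
  seqs <- as_rna(seqs)[order(names(seqs))]
  list(concat = paste(seqs, collapse = "#"),
       starts = cumsum(c(1L, nchar(seqs) + 1L))[seq_along(seqs)],
       names = names(seqs))
}

find_exact <- function(read, index) {
  g <- gregexpr(read, index$concat, fixed = TRUE)[[1]]
  if (g[1] == -1) return(NULL)
  pos <- as.integer(g)
  k <- findInterval(pos, index$starts)
  local <- pos - index$starts[k] + 1L
  data.frame(seq_id = index$names[k], start = local,
             end = local + nchar(read) - 1L, stringsAsFactors = FALSE)
}

#' Mask the 3' adapter and filter reads by length and quality
#'
#' The leftmost exact occurrence of the adapter prefix (the first 8 nt, or
#' the full adapter if shorter) is clipped together with everything 3' of
#' it.  Reads containing N (the low-quality rule for constant-quality
#' libraries) or with clipped length outside `[min_len, max_len]` are
#' removed.  Read order is preserved.
#'
#' @param reads a `read_set` (or data frame with `id`, `sequence`).
#' @param adapter 3' adapter sequence, at least 6 nt.
#' @param min_len,max_len clipped-insert length bounds (nt).
#' @param prefix_len adapter prefix length used for matching (default 8).
#' @return filtered `read_set` with clipped sequences.
#' @export
mask_and_filter <- function(reads, adapter, min_len = 13L, max_len = 28L,
                            prefix_len = 8L) {
  if (missing(adapter) || !nzchar(adapter)) stop("adapter must be given")
  if (nchar(adapter) < 6) stop("adapter must be at least 6 nt")
  pre <- toupper(substr(adapter, 1L, min(prefix_len, nchar(adapter))))
  seqs <- toupper(reads$sequence)
  hit <- regexpr(pre, seqs, fixed = TRUE)
  clipped <- ifelse(hit > 0, substr(seqs, 1L, hit - 1L), seqs)
  keep <- !grepl("N", clipped, fixed = TRUE) &
    nchar(clipped) >= min_len & nchar(clipped) <= max_len
  out <- reads[keep, , drop = FALSE]
  out$sequence <- clipped[keep]
  out$length <- nchar(out$sequence)
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Assign reads to kingdom transcriptomes by exact sense-strand match
#'
#' A read is assigned to a kingdom when it occurs verbatim (sense strand) in
#' at least one transcript of that kingdom; reads present in both kingdoms
#' are `ambiguous`, reads present in neither are `unassigned`.
#'
#' @param reads a `read_set` of clean (masked, filtered) reads.
#' @param bundle a [reference_bundle()] (only the transcript slots are used).
#' @return list with `assignments` (per-read data frame: `id`, `class`,
#'   `feature_id`) and `table` (per-class counts).
#' @export
assign_reads <- function(reads, bundle) {
  if (!length(bundle$plant_transcripts) && !length(bundle$animal_transcripts))
    stop("reference transcripts are empty")
  n <- nrow(reads)
  if (n == 0)
    return(list(assignments = data.frame(id = character(0),
                                         class = character(0),
                                         feature_id = character(0)),
                table = data.frame(class = character(0), n = integer(0))))
  useq <- unique(as_rna(reads$sequence))
  plant <- seq_index(bundle$plant_transcripts)
  animal <- seq_index(bundle$animal_transcripts)
  first_hit <- function(s, idx) {
    if (is.null(idx)) return(NA_character_)
    hit <- regexpr(s, idx$concat, fixed = TRUE)
    if (hit < 0) return(NA_character_)
    # index is in lexicographic id order, so the leftmost occurrence falls
    # in the lexicographically smallest matching transcript
    idx$names[findInterval(as.integer(hit), idx$starts)]
  }
  phit <- vapply(useq, first_hit, character(1), idx = plant)
  ahit <- vapply(useq, first_hit, character(1), idx = animal)
  ucl <- ifelse(!is.na(phit) & !is.na(ahit), "ambiguous",
         ifelse(!is.na(phit), "plant_transcript",
         ifelse(!is.na(ahit), "animal_transcript", "unassigned")))
  ufeat <- ifelse(ucl == "plant_transcript", phit,
           ifelse(ucl == "animal_transcript", ahit, "*"))
  idx <- match(as_rna(reads$sequence), useq)
  assignments <- data.frame(id = reads$id, class = ucl[idx],
                            feature_id = ufeat[idx],
                            stringsAsFactors = FALSE)
  tab <- as.data.frame(table(class = assignments$class),
                       stringsAsFactors = FALSE)
  names(tab) <- c("class", "n")
  list(assignments = assignments, table = tab)
}

#' Match a read against miRNA precursors under the shift rule
#'
#' A read is a miRNA hit when it is an exact, gap-free substring of a
#' precursor (the zero-mismatch, zero-gap optimum of a Smith-Waterman local
#' alignment with match +1, mismatch -3, gap -5 covering the full read) and
#' each terminus of its aligned interval lies within `max_shift` nt of an
#' annotated mature terminus on that precursor.  All qualifying
#' (precursor, mature) pairs are returned.
#'
#' @param read a single read sequence (character).
#' @param precursors named character vector of precursor sequences.
#' @param matures mature-annotation data frame (`precursor_id`, `mature_id`,
#'   `start`, `end`, optional `kingdom`).
#' @param max_shift maximum terminus deviation in nt (default 2).
#' @param index optional prebuilt precursor index (internal use, lets a
#'   caller amortize the index over many reads).
#' @return data frame `precursor_id`, `mature_id`, `shift5`, `shift3`,
#'   `kingdom` (zero rows if no hit).
#' @export
match_mirna <- function(read, precursors, matures, max_shift = 2L,
                        index = NULL) {
  s <- as_rna(read)
  out <- data.frame(precursor_id = character(0), mature_id = character(0),
                    shift5 = integer(0), shift3 = integer(0),
                    kingdom = character(0), stringsAsFactors = FALSE)
  if (grepl("[^ACGU]", s)) return(out)
  if (is.null(index)) index <- seq_index(precursors)
  occ <- find_exact(s, index)
  if (is.null(occ)) return(out)
  rows <- list()
  for (h in seq_len(nrow(occ))) {
    pid <- occ$seq_id[h]
    ann <- matures[matures$precursor_id == pid, , drop = FALSE]
    if (!nrow(ann)) next
    for (r in seq_len(nrow(ann))) {
      d5 <- occ$start[h] - ann$start[r]
      d3 <- occ$end[h] - ann$end[r]
      if (abs(d5) <= max_shift && abs(d3) <= max_shift)
        rows[[length(rows) + 1L]] <- data.frame(
          precursor_id = pid, mature_id = ann$mature_id[r],
          shift5 = d5, shift3 = d3,
          kingdom = if ("kingdom" %in% names(ann)) ann$kingdom[r]
                    else NA_character_,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out
}

#' Normalize a count table to a fixed library size
#'
#' `normalized_i = raw_i * total / sum(raw)` per sample; fractional values
#' are kept so the per-sample sum equals `total` exactly.  Idempotent on the
#' normalized column and invariant to pre-scaling of the raw counts.
#'
#' @param table data frame with columns `sample_id`, `raw_count` (and
#'   anything else, preserved).
#' @param total target library size (default 1e7 reads).
#' @return the table with a `normalized` column (reads per `total`).
#' @export
normalize_counts <- function(table, total = 1e7) {
  stopifnot(all(c("sample_id", "raw_count") %in% names(table)))
  if (any(table$raw_count < 0)) stop("raw counts must be non-negative")
  sums <- tapply(table$raw_count, table$sample_id, sum)
  if (any(sums <= 0))
    stop(sprintf("empty library for sample(s): %s",
                 paste(names(sums)[sums <= 0], collapse = ", ")))
  table$normalized <- table$raw_count * total /
    as.numeric(sums[table$sample_id])
  table
}

#' Read-length histogram
#'
#' Counts per integer length over a closed range; reads outside the range
#' are pooled into flagged boundary bins.
#'
#' @param reads a `read_set` (or data frame with a `sequence` column).
#' @param range length interval, default 9-33 nt.
#' @return data frame `length` (integer, plus `<min` / `>max` pool rows),
#'   `count`, `pooled`.
#' @export
length_histogram <- function(reads, range = c(9L, 33L)) {
  lens <- nchar(reads$sequence)
  bins <- range[1]:range[2]
  counts <- vapply(bins, function(b) sum(lens == b), integer(1))
  out <- data.frame(length = as.character(bins), count = counts,
                    pooled = FALSE, stringsAsFactors = FALSE)
  rbind(out,
        data.frame(length = c(sprintf("<%d", range[1]),
                              sprintf(">%d", range[2])),
                   count = c(sum(lens < range[1]), sum(lens > range[2])),
                   pooled = TRUE, stringsAsFactors = FALSE))
}

#' Full small-RNA census of one library
#'
#' Runs the chain mask/filter -> miRNA matching -> transcript assignment ->
#' normalization.  Classification precedence: a read with a qualifying
#' mature hit is a miRNA read (plant or animal by the precursor's kingdom;
#' hits in both kingdoms make it `ambiguous`); otherwise the exact
#' transcript assignment decides; otherwise `unassigned`.  A read with
#' several qualifying matures in one kingdom is counted once, attributed to
#' the mature with the smallest total terminus shift (ties broken by
#' lexicographic mature id).  Every filtered-in read contributes to exactly
#' one class, so class counts are conserved.
#'
#' @param reads a `read_set` (raw, adapter still present).
#' @param bundle a [reference_bundle()].
#' @param adapter 3' adapter; defaults to the simulator default.
#' @param min_len,max_len insert length window (nt).
#' @param max_shift mature terminus shift tolerance (nt).
#' @param total normalization target library size.
#' @param sample_id sample label for the count table.
#' @return object of class `srna_census`: list with `counts` (sample_id,
#'   feature_id, class, raw_count, normalized), `assignments` (per read),
#'   `histogram`, `n_input`, `n_clean`.
#' @export
census <- function(reads, bundle, adapter = sim_config()$adapter,
                   min_len = 13L, max_len = 28L, max_shift = 2L,
                   total = 1e7, sample_id = "S1") {
  n_input <- nrow(reads)
  clean <- mask_and_filter(reads, adapter, min_len, max_len)
  hist <- length_histogram(clean)
  n_clean <- nrow(clean)
  cls <- character(n_clean)
  feat <- character(n_clean)
  if (n_clean) {
    useq <- unique(as_rna(clean$sequence))
    pre_idx <- seq_index(bundle$precursors)
    uhits <- lapply(useq, match_mirna, precursors = bundle$precursors,
                    matures = bundle$matures, max_shift = max_shift,
                    index = pre_idx)
    ucls <- ufeat <- rep(NA_character_, length(useq))
    for (k in seq_along(useq)) {
      h <- uhits[[k]]
      if (!nrow(h)) next
      kgs <- unique(h$kingdom)
      if (length(kgs) > 1) {
        ucls[k] <- "ambiguous"; ufeat[k] <- "*"
      } else {
        ucls[k] <- paste0(kgs, "_miRNA")
        h <- h[order(abs(h$shift5) + abs(h$shift3), h$mature_id), ]
        ufeat[k] <- h$mature_id[1]
      }
    }
    idx <- match(as_rna(clean$sequence), useq)
    cls <- ucls[idx]; feat <- ufeat[idx]
    need <- is.na(cls)
    if (any(need)) {
      asg <- assign_reads(clean[need, , drop = FALSE], bundle)
      cls[need] <- asg$assignments$class
      feat[need] <- asg$assignments$feature_id
    }
  }
  counts <- if (n_clean) {
    agg <- stats::aggregate(list(raw_count = rep(1L, n_clean)),
                            by = list(feature_id = feat, class = cls),
                            FUN = sum)
    agg <- agg[order(agg$class, agg$feature_id), ]
    cbind(sample_id = sample_id, agg)
  } else data.frame(sample_id = character(0), feature_id = character(0),
                    class = character(0), raw_count = integer(0))
  if (nrow(counts)) counts <- normalize_counts(counts, total)
  else counts$normalized <- numeric(0)
  rownames(counts) <- NULL
  structure(list(counts = counts,
                 assignments = data.frame(id = clean$id, class = cls,
                                          feature_id = feat,
                                          stringsAsFactors = FALSE),
                 histogram = hist, n_input = n_input, n_clean = n_clean,
                 total = total, sample_id = sample_id),
            class = "srna_census")
}

#' @export
print.srna_census <- function(x, ...) {
  cat(sprintf("<srna_census> sample %s: %d reads in, %d clean\n",
              x$sample_id, x$n_input, x$n_clean))
  if (nrow(x$counts)) {
    byc <- tapply(x$counts$raw_count, x$counts$class, sum)
    for (cl in names(byc))
      cat(sprintf("  %-18s %8d reads\n", cl, byc[[cl]]))
    cat(sprintf("  normalized sum = %s (target %s)\n",
                format(sum(x$counts$normalized), big.mark = ","),
                format(x$total, big.mark = ",", scientific = FALSE)))
  }
  invisible(x)
}
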