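#' @useDynLib pollenmir, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm coef rnorm runif aov t.test pchisq p.adjust setNames
#'   var cor complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide sequence to RNA uppercase
#'
#' All sequence comparisons in this package are alphabet-agnostic: reads are
#' carried in DNA (T), references may use either, and everything is converted
#' to RNA (U) internally before matching or thermodynamics.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over \{A, C, G, U, N\}.
#' @export
as_rna <- function(x) chartr("tT", "uU", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("uU", "tT", toupper(x))

base_codes <- function(seq) {
  # A=0 C=1 G=2 U=3; anything else (incl. N) = -2, never pairable
  m <- match(strsplit(as_rna(seq), "")[[1]], RNA_BASES)
  m[is.na(m)] <- -1L
  as.integer(m - 1L)
}

check_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGUN]", as_rna(x))
  if (any(bad))
    stop(sprintf("%s contains non-nucleotide characters: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Reverse complement (RNA alphabet)
#' @param x character vector of sequences.
#' @return reverse complement, RNA alphabet.
#' @export
rev_comp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", as_rna(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_seq <- function(n, len, alphabet = c("A", "C", "G", "U"),
                       prob = NULL) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len[(i - 1L) %% length(len) + 1L],
                 replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

#' Read and write FASTA via Biostrings
#'
#' Thin wrappers so every module reads and writes the standard formats the
#' same way.  Sequences are returned as plain named character vectors.
#'
#' @param path file path.
#' @param seqs named character vector of sequences (for writers).
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read/write small-RNA reads as FASTQ (Phred 33, constant quality)
#'
#' @param reads a `read_set` data frame (or any data frame with `id` and
#'   `sequence` columns).
#' @param path file path.
#' @param quality_char constant per-base quality character (default "I",
#'   Phred 40).
#' @return `read_fastq` returns a `read_set` with unknown truth labels.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  seqs <- Biostrings::DNAStringSet(as_dna(reads$sequence))
  names(seqs) <- reads$id
  quals <- Biostrings::BStringSet(strrep(quality_char,
                                         Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  read_set(data.frame(id = names(x), sequence = as.character(x),
                      stringsAsFactors = FALSE))
}

read_set <- function(df) {
  stopifnot(all(c("id", "sequence") %in% names(df)))
  df$length <- nchar(df$sequence)
  rownames(df) <- NULL
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads, lengths %s\n", nrow(x),
              if (nrow(x)) paste(range(x$length), collapse = "-") else "-"))
  if ("truth_class" %in% names(x))
    print(table(x$truth_class))
  invisible(x)
}
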