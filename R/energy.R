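# Intermolecular RNA:RNA hybrid thermodynamics.
#
# The model is the classic nearest-neighbor hybrid energy: a duplex is an
# ordered, antiparallel set of base pairs (miRNA positions increase while the
# site positions decrease), scored as
#
#   dG = duplex_init + sum(stack | bulge | interior-loop terms)
#        + terminal AU/GU penalties at both duplex ends
#
# with no intramolecular structure, no dangling-end terms, and loops capped
# at max_loop unpaired nucleotides per strand.  A finite-energy duplex must
# contain at least two stacked (adjacent) pairs; single isolated pairs are
# never reported.

#' Load a nearest-neighbor free-energy parameter table
#'
#' Parameters are read from a plain-text TSV with columns
#' `category` (stack, bulge, interior, misc), `key` and `dg` (kcal/mol at
#' 37 C).  Stack keys are doublets written `XY/ZW`: top strand 5'XY3' over
#' bottom strand 3'ZW5', with X:Z and Y:W the pairs.  The package bundles a
#' Turner-2004-style table (`inst/extdata/nn_dg37.tsv`); any table with the
#' same layout can be swapped in.
#'
#' @param path path to a parameter TSV; default the bundled table.
#' @return an object of class `nn_params`: list with `stack` (6x6 matrix over
#'   pair ids AU, UA, CG, GC, GU, UG), `bulge` and `interior` loop-initiation
#'   vectors indexed by unpaired length, `duplex_init`, `terminal_au`,
#'   `asym_per_nt`, `asym_cap` and `max_loop`.
#' @export
nn_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nn_dg37.tsv", package = "pollenmir")
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
  stopifnot(all(c("category", "key", "dg") %in% names(tab)))
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  st <- tab[tab$category == "stack", ]
  if (nrow(st) != 36) stop("stack table must contain all 36 doublets")
  S <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  for (r in seq_len(nrow(st))) {
    k <- st$key[r]  # "XY/ZW"
    p1 <- paste0(substr(k, 1, 1), substr(k, 4, 4))
    p2 <- paste0(substr(k, 2, 2), substr(k, 5, 5))
    S[p1, p2] <- st$dg[r]
  }
  if (anyNA(S)) stop("incomplete stack table")
  wc <- c("AU", "UA", "CG", "GC")
  if (any(S[wc, wc] >= 0))
    stop("Watson-Crick stack energies must be negative")
  bu <- tab[tab$category == "bulge", ]
  bulge <- bu$dg[order(as.integer(bu$key))]
  it <- tab[tab$category == "interior", ]
  interior <- it$dg[order(as.integer(it$key))]
  ms <- setNames(tab$dg[tab$category == "misc"],
                 tab$key[tab$category == "misc"])
  if (any(c(bulge, interior, ms["terminal_au"], ms["asym_per_nt"]) < 0))
    stop("loop and terminal penalties must be non-negative")
  structure(list(stack = S, bulge = bulge, interior = interior,
                 duplex_init = unname(ms["duplex_init"]),
                 terminal_au = unname(ms["terminal_au"]),
                 asym_per_nt = unname(ms["asym_per_nt"]),
                 asym_cap = unname(ms["asym_cap"]),
                 max_loop = as.integer(ms["max_loop"])),
            class = "nn_params")
}

#' Seed-pairing requirement for target sites
#'
#' The seed is the miRNA 5' element that dominates target recognition.  A
#' duplex is `seed_paired` when every requested miRNA position is paired
#' contiguously (no loops between consecutive seed pairs).  G:U wobbles are
#' permitted in the seed by default, mirroring the observation that
#' functional plant-miRNA sites in animal transcripts can carry a seed
#' wobble.
#'
#' @param positions miRNA positions (1-based from the 5' end) that must be
#'   paired; default 2:7.
#' @param allow_GU logical; may seed pairs be G:U wobbles?
#' @return an object of class `seed_spec`.
#' @export
seed_spec <- function(positions = 2:7, allow_GU = TRUE) {
  positions <- sort(unique(as.integer(positions)))
  if (any(positions < 1)) stop("seed positions must be >= 1")
  if (any(positions > 8))
    stop("seed positions are restricted to the miRNA 5' region (<= 8)")
  structure(list(positions = positions, allow_GU = allow_GU),
            class = "seed_spec")
}

PAIR_IDS <- c(AU = 0L, UA = 1L, CG = 2L, GC = 3L, GU = 4L, UG = 5L)

pair_type <- function(a, b) {
  # a, b single RNA characters; returns "WC", "GU" or NA
  p <- paste0(a, b)
  if (p %in% c("AU", "UA", "CG", "GC")) return("WC")
  if (p %in% c("GU", "UG")) return("GU")
  NA_character_
}

seed_paired <- function(pairs, mirna, site, seed) {
  # pairs: matrix (mirna_pos, site_pos), ordered by mirna_pos
  if (nrow(pairs) == 0) return(FALSE)
  if (max(seed$positions) > nchar(mirna)) return(FALSE)
  m <- strsplit(as_rna(mirna), "")[[1]]
  s <- strsplit(as_rna(site), "")[[1]]
  idx <- match(seed$positions, pairs[, 1])
  if (anyNA(idx)) return(FALSE)
  # contiguity: consecutive seed positions pair consecutive site positions
  if (length(idx) > 1) {
    dj <- diff(pairs[idx, 2])
    di <- diff(pairs[idx, 1])
    if (any(di != 1L) || any(dj != -1L)) return(FALSE)
  }
  if (!seed$allow_GU) {
    types <- mapply(function(i, j) pair_type(m[i], s[j]),
                    pairs[idx, 1], pairs[idx, 2])
    if (any(types != "WC")) return(FALSE)
  }
  TRUE
}

#' Minimum-free-energy miRNA:site hybrid
#'
#' Computes the lowest-energy antiparallel intermolecular duplex between a
#' miRNA and a candidate target site under the nearest-neighbor model:
#' allowed pairs AU/UA/CG/GC/GU/UG, stacked helices, bulges and interior
#' loops up to `params$max_loop` unpaired nt per strand, no intramolecular
#' pairing, terminal AU/GU penalties at both duplex ends, no dangling ends.
#' Structures must contain at least two stacked pairs; if none exists the
#' energy is `+Inf` with an empty structure.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param site candidate site sequence, 5'->3'.  Must be no longer than
#'   `nchar(mirna) + 2 * params$max_loop`.
#' @param params an [nn_params()] table.
#' @param seed a [seed_spec()]; used only to annotate `seed_paired`.
#' @return an object of class `duplex_result`: list with `dG` (kcal/mol),
#'   `pairs` (matrix of 1-based (mirna_pos, site_pos), both counted from
#'   their own 5' ends), `structure` (plain-text duplex rendering),
#'   `seed_paired`, `mirna`, `site`.
#' @examples
#' d <- duplex_mfe("UCGAUAAACCUCUGCAUCCAG",
#'                 rev_comp("UCGAUAAACCUCUGCAUCCAG"))
#' d$dG
#' @export
duplex_mfe <- function(mirna, site, params = nn_params(),
                       seed = seed_spec()) {
  check_rna(mirna, "miRNA")
  check_rna(site, "site")
  if (!nchar(mirna) || !nchar(site)) stop("sequences must be non-empty")
  if (nchar(site) > nchar(mirna) + 2L * params$max_loop)
    stop("site longer than miRNA + 2*max_loop; use scan_sites() for mRNAs")
  res <- .duplex_mfe_cpp(base_codes(mirna), base_codes(site),
                         params$stack, params$bulge, params$interior,
                         params$duplex_init, params$terminal_au,
                         params$asym_per_nt, params$asym_cap,
                         params$max_loop)
  pairs <- res$pairs
  colnames(pairs) <- c("mirna_pos", "site_pos")
  structure(list(dG = res$dg, pairs = pairs,
                 structure = render_duplex(pairs, mirna, site),
                 seed_paired = seed_paired(pairs, mirna, site, seed),
                 mirna = as_rna(mirna), site = as_rna(site)),
            class = "duplex_result")
}

#' Energy of an explicit duplex structure (audit)
#'
#' Recomputes the free energy of a given pairing set under the same model as
#' [duplex_mfe()].  Used to audit reported structures and by the
#' brute-force oracle.
#'
#' @param pairs matrix of (mirna_pos, site_pos), ordered with mirna positions
#'   strictly increasing and site positions strictly decreasing.
#' @inheritParams duplex_mfe
#' @return energy in kcal/mol, or `+Inf` for an illegal/stackless structure.
#' @export
duplex_energy <- function(pairs, mirna, site, params = nn_params()) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2)
  k <- nrow(pairs)
  if (k < 2) return(Inf)
  m <- strsplit(as_rna(mirna), "")[[1]]
  s <- strsplit(as_rna(site), "")[[1]]
  if (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) >= 0)) return(Inf)
  pr <- character(k)
  for (t in seq_len(k)) {
    pt <- paste0(m[pairs[t, 1]], s[pairs[t, 2]])
    if (!pt %in% names(PAIR_IDS)) return(Inf)
    pr[t] <- pt
  }
  e <- params$duplex_init
  if (pr[1] %in% c("AU", "UA", "GU", "UG")) e <- e + params$terminal_au
  if (pr[k] %in% c("AU", "UA", "GU", "UG")) e <- e + params$terminal_au
  has_stack <- FALSE
  for (t in seq_len(k - 1)) {
    a <- pairs[t + 1, 1] - pairs[t, 1] - 1L
    b <- pairs[t, 2] - pairs[t + 1, 2] - 1L
    if (a > params$max_loop || b > params$max_loop) return(Inf)
    if (a == 0 && b == 0) {
      e <- e + params$stack[pr[t], pr[t + 1]]
      has_stack <- TRUE
    } else if (a == 0 || b == 0) {
      len <- a + b
      if (len > length(params$bulge)) return(Inf)
      e <- e + params$bulge[len]
    } else {
      len <- a + b
      if (len - 1 > length(params$interior)) return(Inf)
      e <- e + params$interior[len - 1] +
        min(params$asym_cap, params$asym_per_nt * abs(a - b))
    }
  }
  if (!has_stack) return(Inf)
  e
}

#' Brute-force duplex enumeration (test oracle)
#'
#' Enumerates every legal antiparallel pairing set between two short strands
#' and returns the exact minimum energy.  Exists to verify [duplex_mfe()];
#' it is deliberately independent of the dynamic program.
#'
#' @inheritParams duplex_mfe
#' @return minimum energy in kcal/mol (`+Inf` if no legal structure).
#' @export
enumerate_structures <- function(mirna, site, params = nn_params()) {
  check_rna(mirna, "miRNA")
  check_rna(site, "site")
  n <- nchar(mirna); L <- nchar(site)
  if (n + L > 18) stop("oracle restricted to combined length <= 18 nt")
  m <- strsplit(as_rna(mirna), "")[[1]]
  s <- strsplit(as_rna(site), "")[[1]]
  cand <- which(outer(m, s, function(a, b)
    paste0(a, b) %in% names(PAIR_IDS)), arr.ind = TRUE)
  if (nrow(cand) == 0) return(Inf)
  cand <- cand[order(cand[, 1], -cand[, 2]), , drop = FALSE]
  best <- Inf
  recurse <- function(chain, from) {
    if (nrow(chain) >= 2) {
      e <- duplex_energy(chain, mirna, site, params)
      if (e < best) best <<- e
    }
    if (from > nrow(cand)) return(invisible())
    for (t in from:nrow(cand)) {
      i <- cand[t, 1]; j <- cand[t, 2]
      if (nrow(chain) == 0 ||
          (i > chain[nrow(chain), 1] && j < chain[nrow(chain), 2] &&
           i - chain[nrow(chain), 1] - 1 <= params$max_loop &&
           chain[nrow(chain), 2] - j - 1 <= params$max_loop)) {
        recurse(rbind(chain, c(i, j)), t + 1)
      }
    }
  }
  recurse(matrix(numeric(0), ncol = 2), 1)
  best
}

render_duplex <- function(pairs, mirna, site) {
  if (nrow(pairs) == 0) return("")
  m <- strsplit(as_rna(mirna), "")[[1]]
  s <- strsplit(as_rna(site), "")[[1]]
  top <- mid <- bot <- character(0)
  # walk the duplex from the miRNA 5' end; site runs 3'->5' on top
  prev <- NULL
  for (t in seq_len(nrow(pairs))) {
    i <- pairs[t, 1]; j <- pairs[t, 2]
    if (!is.null(prev)) {
      gi <- if (i - prev[1] > 1) (prev[1] + 1):(i - 1) else integer(0)
      gj <- if (prev[2] - j > 1) (prev[2] - 1):(j + 1) else integer(0)
      w <- max(length(gi), length(gj))
      if (w > 0) {
        top <- c(top, formatC(paste(s[gj], collapse = ""), width = -w))
        bot <- c(bot, formatC(paste(m[gi], collapse = ""), width = -w))
        mid <- c(mid, strrep(" ", w))
      }
    }
    top <- c(top, s[j]); bot <- c(bot, m[i])
    mid <- c(mid, if (pair_type(m[i], s[j]) == "WC") "|" else ":")
    prev <- c(i, j)
  }
  gsub(" +\n", "\n", paste0(
    "site  3' ", paste(top, collapse = ""), " 5'\n",
    "         ", paste(mid, collapse = ""), "\n",
    "miRNA 5' ", paste(bot, collapse = ""), " 3'"))
}

#' @export
print.duplex_result <- function(x, ...) {
  cat(sprintf("<duplex_result> dG = %s kcal/mol, %d pairs, seed_paired = %s\n",
              format(x$dG), nrow(x$pairs), x$seed_paired))
  if (nzchar(x$structure)) cat(x$structure, "\n")
  invisible(x)
}

#' Scan an mRNA for miRNA binding sites below an energy cutoff
#'
#' Slides a window of width `nchar(mirna) + params$max_loop` along the mRNA
#' (1-nt steps), computes the hybrid MFE in each window, and reports merged,
#' non-overlapping sites whose energy passes the cutoff and whose duplex has
#' the seed paired.  Windows that cannot host a contiguous seed helix are
#' pruned before the dynamic program runs.
#'
#' @inheritParams duplex_mfe
#' @param mrna mRNA sequence, 5'->3' (may be long).
#' @param cutoff report sites with `dG <= cutoff` (kcal/mol); default -17.
#' @return data frame (`site_start`, `site_end`, `dG`, `seed_paired`,
#'   `structure`) with 1-based inclusive mRNA coordinates; the matched
#'   `duplex_result` objects are attached as attribute `"duplexes"`.
#' @export
scan_sites <- function(mirna, mrna, params = nn_params(),
                       seed = seed_spec(), cutoff = -17) {
  check_rna(mirna, "miRNA")
  check_rna(mrna, "mRNA")
  n <- nchar(mirna); L <- nchar(mrna)
  if (L < n) stop("mRNA shorter than miRNA")
  width <- min(L, n + params$max_loop)
  empty <- data.frame(site_start = integer(0), site_end = integer(0),
                      dG = numeric(0), seed_paired = logical(0),
                      structure = character(0), stringsAsFactors = FALSE)
  if (!is.finite(cutoff)) {
    if (cutoff < 0) { attr(empty, "duplexes") <- list(); return(empty) }
  }
  mr <- as_rna(mrna)
  # prune: a reportable site must contain the reverse complement (GU allowed)
  # of the contiguous seed block
  sp <- seed$positions
  block <- substr(as_rna(mirna), min(sp), max(sp))
  partner <- c(A = "U", C = "G", G = if (seed$allow_GU) "[CU]" else "C",
               U = if (seed$allow_GU) "[AG]" else "A")
  pat <- paste(rev(partner[strsplit(block, "")[[1]]]), collapse = "")
  blen <- nchar(block)
  hits <- gregexpr(paste0("(?=", pat, ")"), mr, perl = TRUE)[[1]]
  if (hits[1] == -1) { attr(empty, "duplexes") <- list(); return(empty) }
  starts <- sort(unique(unlist(lapply(as.integer(hits), function(h) {
    lo <- max(1L, h + blen - width)
    hi <- min(h, L - width + 1L)
    if (lo > hi) integer(0) else lo:hi
  }))))
  cand <- list()
  for (st in starts) {
    win <- substr(mr, st, st + width - 1L)
    d <- duplex_mfe(mirna, win, params, seed)
    if (is.finite(d$dG) && d$dG <= cutoff && d$seed_paired) {
      s0 <- st + min(d$pairs[, 2]) - 1L
      s1 <- st + max(d$pairs[, 2]) - 1L
      cand[[length(cand) + 1L]] <-
        list(start = s0, end = s1, dG = d$dG, duplex = d)
    }
  }
  if (!length(cand)) { attr(empty, "duplexes") <- list(); return(empty) }
  # merge overlapping qualifying windows: keep local energy minima
  ord <- order(vapply(cand, `[[`, numeric(1), "dG"),
               vapply(cand, `[[`, numeric(1), "start"))
  kept <- list()
  for (k in ord) {
    ck <- cand[[k]]
    overlaps <- any(vapply(kept, function(z)
      ck$start <= z$end && z$start <= ck$end, logical(1)))
    if (!overlaps) kept[[length(kept) + 1L]] <- ck
  }
  kept <- kept[order(vapply(kept, `[[`, numeric(1), "start"))]
  out <- data.frame(
    site_start = vapply(kept, `[[`, numeric(1), "start"),
    site_end = vapply(kept, `[[`, numeric(1), "end"),
    dG = vapply(kept, `[[`, numeric(1), "dG"),
    seed_paired = TRUE,
    structure = vapply(kept, function(z) z$duplex$structure, character(1)),
    stringsAsFactors = FALSE)
  attr(out, "duplexes") <- lapply(kept, `[[`, "duplex")
  out
}
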