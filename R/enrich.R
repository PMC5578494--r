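# GO enrichment: ortholog mapping, per-term chi-square tests, network export.

#' Map bee genes to fly orthologs through a provided table
#'
#' @param genes character vector of bee gene ids.
#' @param table ortholog data frame (`bee_gene_id`, `fly_gene_id`);
#'   many-to-one is allowed, duplicates are collapsed.
#' @return list with `mapped` (unique fly ids) and `unmapped` (bee ids with
#'   no table entry — reported, never silently dropped).
#' @export
map_orthologs <- function(genes, table) {
  stopifnot(all(c("bee_gene_id", "fly_gene_id") %in% names(table)))
  table <- unique(table[nzchar(table$bee_gene_id) &
                          nzchar(table$fly_gene_id), ])
  genes <- unique(genes)
  hit <- table$fly_gene_id[table$bee_gene_id %in% genes]
  list(mapped = sort(unique(hit)),
       unmapped = sort(setdiff(genes, table$bee_gene_id)))
}

chisq_2x2 <- function(k_t, n_t, k_b, n_b) {
  # 2x2 Pearson chi-square without continuity correction, closed form
  O <- matrix(c(k_t, n_t - k_t, k_b - k_t, (n_b - n_t) - (k_b - k_t)),
              2, 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (any(E == 0)) return(NULL)
  sum((O - E)^2 / E)
}

#' Per-term chi-square GO enrichment
#'
#' For each GO term, builds the 2x2 table of in-term vs not-in-term counts
#' for the target set against the rest of the background and computes the
#' Pearson chi-square statistic (no continuity correction) with a
#' 1-degree-of-freedom p-value.  A term is `enriched` when p < alpha and the
#' target in-term proportion exceeds the background proportion.  No
#' multiple-testing correction is applied to the decision (matching the
#' p < 0.05 criterion); a Benjamini-Hochberg column is emitted alongside for
#' transparency.  Terms with a zero expected cell are skipped with a logged
#' reason.
#'
#' @param targets character vector of target gene ids (must be within the
#'   background).
#' @param background character vector of background gene ids (>= 2 after
#'   deduplication).
#' @param annotations data frame `gene_id`, `go_id`, `go_name`.
#' @param alpha significance level (default 0.05).
#' @return data frame of class `go_enrichment`: `go_id`, `go_name`,
#'   `k_target`, `n_target`, `k_background`, `n_background`, `chi2`, `p`,
#'   `p_bh`, `enriched`; skipped terms in attribute `"skipped"`.
#' @export
enrich_chisq <- function(targets, background, annotations, alpha = 0.05) {
  targets <- unique(targets)
  background <- unique(background)
  if (length(background) < 2) stop("background must contain >= 2 genes")
  if (!all(targets %in% background))
    stop("targets must be a subset of the background")
  stopifnot(all(c("gene_id", "go_id", "go_name") %in% names(annotations)))
  terms <- unique(annotations[, c("go_id", "go_name")])
  n_t <- length(targets)
  n_b <- length(background)
  rows <- list(); skipped <- character(0)
  for (r in seq_len(nrow(terms))) {
    in_term <- unique(annotations$gene_id[annotations$go_id ==
                                            terms$go_id[r]])
    k_t <- length(intersect(in_term, targets))
    k_b <- length(intersect(in_term, background))
    chi2 <- chisq_2x2(k_t, n_t, k_b, n_b)
    if (is.null(chi2)) {
      skipped <- c(skipped,
                   sprintf("%s: zero expected cell", terms$go_id[r]))
      next
    }
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      go_id = terms$go_id[r], go_name = terms$go_name[r],
      k_target = k_t, n_target = n_t, k_background = k_b,
      n_background = n_b, chi2 = chi2, p = p,
      enriched = p < alpha & (k_t / n_t > k_b / n_b),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(go_id = character(0), go_name = character(0),
                  k_target = integer(0), n_target = integer(0),
                  k_background = integer(0), n_background = integer(0),
                  chi2 = numeric(0), p = numeric(0), enriched = logical(0))
  out$p_bh <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$go_id), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("go_enrichment", "data.frame")
  out
}

#' Export an enriched-term association network
#'
#' Nodes are enriched terms sized by -log10(p); edges connect terms sharing
#' at least one target gene, weighted by the Jaccard index of their target
#' gene sets.  The edge list is importable by standard network tools.
#'
#' @param rows a `go_enrichment` table.
#' @param annotations the annotation data frame used for enrichment.
#' @param targets the target gene ids.
#' @return list with `nodes` (`go_id`, `go_name`, `size`) and `edges`
#'   (`source`, `target`, `weight`).
#' @export
export_network <- function(rows, annotations, targets) {
  enr <- rows[rows$enriched, , drop = FALSE]
  if (!nrow(enr)) stop("no enriched terms to export")
  gene_sets <- lapply(enr$go_id, function(g)
    intersect(unique(annotations$gene_id[annotations$go_id == g]), targets))
  names(gene_sets) <- enr$go_id
  nodes <- data.frame(go_id = enr$go_id, go_name = enr$go_name,
                      size = -log10(enr$p), stringsAsFactors = FALSE)
  edges <- list()
  if (nrow(enr) > 1) {
    cmb <- utils::combn(seq_len(nrow(enr)), 2)
    for (c in seq_len(ncol(cmb))) {
      a <- gene_sets[[cmb[1, c]]]; b <- gene_sets[[cmb[2, c]]]
      inter <- length(intersect(a, b))
      if (inter > 0)
        edges[[length(edges) + 1L]] <- data.frame(
          source = enr$go_id[cmb[1, c]], target = enr$go_id[cmb[2, c]],
          weight = inter / length(union(a, b)), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
  else data.frame(source = character(0), target = character(0),
                  weight = numeric(0))
  list(nodes = nodes, edges = edges)
}
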