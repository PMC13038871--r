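# Rank-based gene-set activity scoring. Both scores depend only on the
# within-sample ranking of genes, with ties broken lexicographically by gene
# id so results are reproducible bit-for-bit.

#' Single-sample GSEA enrichment scores
#'
#' Per sample, genes are ranked by expression descending. The enrichment
#' score is the summed difference between the weighted in-set cumulative
#' fraction (weights `|rank value|^alpha`, rank value = N..1 from the top)
#' and the uniform out-of-set cumulative fraction, accumulated over all rank
#' positions. NES divides every ES by the global range (max - min) of the ES
#' matrix.
#'
#' @param expr genes x samples [expr_matrix()] (log-normalized expression).
#' @param sets a `gene_set_collection`.
#' @param alpha rank-weighting exponent (>= 0, default 0.25).
#' @param min_overlap minimum genes a set must share with the matrix
#'   (default 5); smaller overlaps are skipped with a warning.
#' @return object of class `pathway_scores`: list with `es`, `nes`
#'   (sets x samples matrices) and `alpha`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, min_overlap = 5) {
  stopifnot(alpha >= 0)
  if (!length(sets)) .stopf("empty gene-set collection")
  genes <- rownames(expr)
  n <- length(genes)
  keep <- vapply(sets, function(s) sum(s$genes %in% genes) >= max(1L, min_overlap),
                 logical(1))
  if (!all(keep))
    .warnf("%d set(s) skipped: overlap below %d", sum(!keep), min_overlap)
  sets <- sets[keep]
  if (!length(sets)) .stopf("no gene set overlaps the expression matrix")

  es <- matrix(0, length(sets), ncol(expr),
               dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    names(x) <- genes
    pos <- .rank_desc(x)                 # position 1 = highest expression
    w_all <- (n - pos + 1)^alpha         # rank value N at the top
    for (k in seq_along(sets)) {
      memb <- genes %in% sets[[k]]$genes
      m <- sum(memb)
      hit_w <- numeric(n); hit_w[pos[memb]] <- w_all[memb]
      miss <- numeric(n); miss[pos[!memb]] <- 1
      p_hit <- cumsum(hit_w) / sum(hit_w)
      p_miss <- cumsum(miss) / (n - m)
      es[k, j] <- sum(p_hit - p_miss)
    }
  }
  rng <- max(es) - min(es)
  nes <- if (rng > 0) es / rng else es
  structure(list(es = es, nes = nes, alpha = alpha), class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("pathway_scores: %d sets x %d samples (alpha = %g)\n",
              nrow(x$es), ncol(x$es), x$alpha))
  invisible(x)
}

#' AUCell-style per-cell gene-set scores
#'
#' Per cell, genes are ranked by expression descending (lexicographic tie
#' break) and the score is the area under the set-gene recovery curve over
#' the top `ceiling(top_fraction * n_genes)` ranks, normalized by the
#' maximal attainable area, so a set fully occupying the top ranks scores 1
#' and a set entirely outside them scores 0.
#'
#' @param expr genes x cells [expr_matrix()].
#' @param sets a `gene_set_collection`.
#' @param top_fraction ranking cutoff as a fraction of genes (default 0.05).
#' @return object of class `cell_signature_scores`: list with `scores`
#'   (sets x cells, values in \[0,1\]) and `top_fraction`.
#' @export
aucell_scores <- function(expr, sets, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  genes <- rownames(expr)
  n <- length(genes)
  ncut <- as.integer(ceiling(top_fraction * n))
  for (nm in names(sets))
    if (length(sets[[nm]]$genes) > n)
      .stopf("set '%s' larger than the gene universe", nm)
  scores <- matrix(0, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    names(x) <- genes
    pos <- .rank_desc(x)
    for (k in seq_along(sets)) {
      memb_pos <- pos[genes %in% sets[[k]]$genes]
      m <- length(memb_pos)
      hits <- integer(ncut)
      inside <- memb_pos[memb_pos <= ncut]
      if (length(inside)) hits[inside] <- 1L
      area <- sum(cumsum(hits))
      max_area <- sum(pmin(seq_len(ncut), m))
      scores[k, j] <- if (max_area > 0) area / max_area else 0
    }
  }
  structure(list(scores = scores, top_fraction = top_fraction),
            class = "cell_signature_scores")
}

#' @export
print.cell_signature_scores <- function(x, ...) {
  cat(sprintf("cell_signature_scores: %d sets x %d cells (top %g%%)\n",
              nrow(x$scores), ncol(x$scores), 100 * x$top_fraction))
  invisible(x)
}
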