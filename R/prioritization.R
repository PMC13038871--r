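# Differential expression at single-cell and bulk thresholds, diffusion
# pseudotime with trend tests, and the four-set evidence intersection that
# nominates driver candidates.

#' Two-group differential expression (Welch t-test on log-scale values)
#'
#' `log2FC` is the difference of group means (case minus control) on the
#' log2 scale. Pass thresholds follow the declared mode:
#' single-cell `q < 0.05 & |log2FC| > 1`; bulk `q < 0.05 & |log2FC| > 0.5`.
#'
#' @param expr genes x samples matrix of log2-scale values.
#' @param groups per-sample group labels.
#' @param case label of the case group (fold changes are case vs control).
#' @param control label of the control group (default: all other samples).
#' @param mode `"single_cell"` or `"bulk"` (threshold preset).
#' @return object of class `de_table`: data.frame with gene, log2fc, t, p,
#'   q, pass; plus the mode and thresholds.
#' @export
differential_expression <- function(expr, groups, case, control = NULL,
                                    mode = c("single_cell", "bulk")) {
  mode <- match.arg(mode)
  thr <- switch(mode, single_cell = c(q = 0.05, lfc = 1),
                bulk = c(q = 0.05, lfc = 0.5))
  a <- groups == case
  b <- if (is.null(control)) !a else groups == control
  if (sum(a) < 3 || sum(b) < 3) .stopf("each group needs >= 3 observations")
  xa <- expr[, a, drop = FALSE]; xb <- expr[, b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  se2 <- va / na + vb / nb
  lfc <- ma - mb
  t_stat <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf * sign(lfc)))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               1)
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              0)
  p[t_stat == 0] <- 1
  q <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(gene = rownames(expr), log2fc = lfc, t = t_stat,
                    p = p, q = q,
                    pass = q < thr["q"] & abs(lfc) > thr["lfc"],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, mode = mode, thresholds = thr),
            class = "de_table")
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("de_table (%s): %d/%d genes pass (q < %g, |log2FC| > %g)\n",
              x$mode, sum(x$table$pass), nrow(x$table),
              x$thresholds["q"], x$thresholds["lfc"]))
  invisible(x)
}

#' Diffusion pseudotime from a root cell
#'
#' Builds a Gaussian-kernel transition matrix on the k-nearest-neighbor
#' graph of the top principal components (adaptive bandwidth: distance to
#' the k-th neighbor), takes the diffusion-map eigendecomposition, and
#' returns each cell's diffusion distance from the root, scaled to a
#' maximum of 1 (root = 0).
#'
#' @param x genes x cells [expr_matrix()] (PCA is applied) or a cells x
#'   dimensions embedding matrix.
#' @param n_components diffusion components used (default 10).
#' @param root root cell id, or `"auto"` to take the cell maximizing
#'   `potency`.
#' @param k_neighbors kNN graph degree (default 15).
#' @param n_pcs principal components kept when `x` is an expression matrix.
#' @param potency optional named per-cell potency score (required for
#'   `root = "auto"`).
#' @param seed RNG seed (PCA sign fixing only; the computation is
#'   deterministic).
#' @return object of class `pseudotime_result`: `pseudotime` (named, in
#'   \[0,1\]), `root`, `n_components`.
#' @export
diffusion_pseudotime <- function(x, n_components = 10, root = "auto",
                                 k_neighbors = 15, n_pcs = 30,
                                 potency = NULL, seed = 1) {
  if (!is.null(attr(x, "mode"))) {
    # genes x cells expression: reduce to principal components
    z <- t(x)
    z <- scale(z, scale = FALSE)
    n_pcs <- min(n_pcs, ncol(z), nrow(z) - 1)
    emb <- stats::prcomp(z, rank. = n_pcs)$x
  } else emb <- as.matrix(x)
  n <- nrow(emb)
  if (n < 2) .stopf("need more than one cell")
  if (n < 10) .stopf("need at least 10 cells")
  cells <- rownames(emb) %||% sprintf("cell%d", seq_len(n))
  rownames(emb) <- cells
  if (identical(root, "auto")) {
    if (is.null(potency))
      .stopf("root = 'auto' requires a per-cell potency score")
    root <- names(potency)[which.max(potency)]
  }
  if (!root %in% cells) .stopf("root cell '%s' not found", root)

  d <- as.matrix(stats::dist(emb))
  k <- min(k_neighbors, n - 1L)
  nn_idx <- apply(d, 1, function(row) order(row)[2:(k + 1L)])
  sigma <- vapply(seq_len(n), function(i) d[i, nn_idx[k, i]], numeric(1))
  sigma <- pmax(sigma, 1e-12)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- nn_idx[, i]
    w[i, j] <- exp(-d[i, j]^2 / (2 * sigma[i] * sigma[j]))
  }
  w <- pmax(w, t(w))   # symmetrize: mutual connectivity
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  if (igraph::components(g)$no > 1)
    .stopf("kNN graph is disconnected; increase k_neighbors")
  deg <- rowSums(w)
  s <- w / sqrt(deg %o% deg)          # symmetrized transition operator
  eig <- eigen(s, symmetric = TRUE)
  m <- min(n_components, n - 1L)
  lam <- eig$values[2:(m + 1L)]
  lam <- pmin(lam, 1 - 1e-10)
  phi <- eig$vectors[, 2:(m + 1L), drop = FALSE] / sqrt(deg)
  # diffusion distance accumulated over all scales: weights lambda/(1-lambda)
  coords <- sweep(phi, 2, lam / (1 - lam), "*")
  ri <- match(root, cells)
  dpt <- sqrt(rowSums(sweep(coords, 2, coords[ri, ], "-")^2))
  pt <- dpt / max(dpt)
  names(pt) <- cells
  structure(list(pseudotime = pt, root = root, n_components = m),
            class = "pseudotime_result")
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf("pseudotime_result: %d cells, root %s, %d components\n",
              length(x$pseudotime), x$root, x$n_components))
  invisible(x)
}

#' Spearman trend test of genes (or pathway scores) against pseudotime
#'
#' Two-sided p-values from the t approximation on rank correlations;
#' constant rows are reported `NA` and excluded from the BH adjustment.
#'
#' @param expr genes (or gene sets) x cells matrix.
#' @param pseudotime a `pseudotime_result` or named numeric vector covering
#'   the cells of `expr`.
#' @return object of class `trend_table`: data.frame with gene, rho, p, q,
#'   direction.
#' @export
trend_test <- function(expr, pseudotime) {
  pt <- if (inherits(pseudotime, "pseudotime_result")) pseudotime$pseudotime
        else pseudotime
  if (!all(colnames(expr) %in% names(pt)))
    .stopf("pseudotime must cover all cells of expr")
  pt <- pt[colnames(expr)]
  n <- ncol(expr)
  if (n < 10) .stopf("need at least 10 cells")
  rp <- rank(pt)
  rho <- apply(expr, 1, function(g) {
    if (stats::sd(g) == 0) return(NA_real_)
    stats::cor(rank(g), rp)
  })
  t_stat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(t_stat), n - 2)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  tab <- data.frame(gene = rownames(expr), rho = rho, p = p, q = q,
                    direction = ifelse(is.na(rho), NA,
                                       ifelse(rho > 0, "up", "down")),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab), class = "trend_table")
}

#' @export
print.trend_table <- function(x, ...) {
  cat(sprintf("trend_table: %d rows, %d with q < 0.05\n",
              nrow(x$table), sum(x$table$q < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Four-set evidence intersection for driver nomination
#'
#' Builds the per-gene evidence table over the union of the four sets
#' (co-expression module genes; single-cell DE genes restricted to a
#' catalog; up-regulated genes in two independent bulk cohorts). The core
#' list is the four-way intersection, optionally restricted to `catalog`.
#'
#' @param module_genes,sc_de_genes,up_cohort1,up_cohort2 character vectors
#'   of gene ids (empty sets permitted).
#' @param catalog optional restriction set (e.g. a deubiquitinase gene
#'   list) applied to the core list.
#' @return object of class `candidate_evidence`: `table` (gene, four
#'   membership flags, evidence_count, core ordered by evidence count then
#'   gene id) and `core` (character vector).
#' @export
intersect_candidates <- function(module_genes, sc_de_genes, up_cohort1,
                                 up_cohort2, catalog = NULL) {
  sets <- list(module = unique(module_genes), sc_de = unique(sc_de_genes),
               up_cohort1 = unique(up_cohort1), up_cohort2 = unique(up_cohort2))
  genes <- sort(unique(unlist(sets)))
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(sets)) tab[[paste0("in_", nm)]] <- genes %in% sets[[nm]]
  tab$evidence_count <- rowSums(tab[, paste0("in_", names(sets))])
  tab$core <- tab$evidence_count == 4L
  if (!is.null(catalog)) tab$core <- tab$core & tab$gene %in% catalog
  tab <- tab[order(-tab$evidence_count, tab$gene), ]
  rownames(tab) <- NULL
  structure(list(table = tab, core = tab$gene[tab$core]),
            class = "candidate_evidence")
}

#' @export
print.candidate_evidence <- function(x, ...) {
  cat(sprintf("candidate_evidence: %d genes, core = {%s}\n",
              nrow(x$table), paste(x$core, collapse = ", ")))
  invisible(x)
}
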