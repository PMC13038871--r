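# Single-cell QC, reference-anchored sliding-window CNV inference, robust-Z
# focal driver calls, silhouette-guided resolution selection and
# tumor-like/normal-like labeling.

#' Quality-control thresholds for single-cell filtering
#'
#' Defaults: 200-10,000 detected genes per cell, at most 20% mitochondrial
#' and 15% hemoglobin transcript fraction.
#' @param min_genes,max_genes detected-gene bounds per cell.
#' @param max_mito_fraction,max_hemoglobin_fraction transcript-fraction caps.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 10000,
                          max_mito_fraction = 0.20,
                          max_hemoglobin_fraction = 0.15) {
  stopifnot(min_genes < max_genes,
            max_mito_fraction > 0, max_mito_fraction <= 1,
            max_hemoglobin_fraction > 0, max_hemoglobin_fraction <= 1)
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Filter cells (and lowly detected genes) from a count matrix
#'
#' Removes cells outside the detected-gene bounds or above the
#' mitochondrial/hemoglobin fraction caps; optionally removes genes detected
#' in fewer than `min_cells_per_gene` of the surviving cells.
#'
#' @param counts genes x cells [expr_matrix()] in counts mode.
#' @param mito_genes,hb_genes gene ids counted toward the mitochondrial /
#'   hemoglobin fractions.
#' @param thresholds a [qc_thresholds()].
#' @param filter_genes drop lowly detected genes (default TRUE).
#' @param min_cells_per_gene detection threshold per gene (default 50).
#' @return list with `counts` (filtered) and `report` (per input cell:
#'   n_genes, mito_fraction, hb_fraction, kept, reason).
#' @export
qc_filter_cells <- function(counts, mito_genes = character(),
                            hb_genes = character(),
                            thresholds = qc_thresholds(),
                            filter_genes = TRUE, min_cells_per_gene = 50) {
  if (expr_mode(counts) != "counts") .stopf("qc_filter_cells expects counts mode")
  tot <- colSums(counts)
  n_genes <- colSums(counts > 0)
  mito <- if (length(mito_genes))
    colSums(counts[rownames(counts) %in% mito_genes, , drop = FALSE]) / pmax(tot, 1)
  else rep(0, ncol(counts))
  hb <- if (length(hb_genes))
    colSums(counts[rownames(counts) %in% hb_genes, , drop = FALSE]) / pmax(tot, 1)
  else rep(0, ncol(counts))
  reason <- rep("", ncol(counts))
  reason[n_genes < thresholds$min_genes] <- "too_few_genes"
  reason[n_genes > thresholds$max_genes] <- "too_many_genes"
  reason[mito > thresholds$max_mito_fraction] <- "high_mito"
  reason[hb > thresholds$max_hemoglobin_fraction] <- "high_hemoglobin"
  keep <- reason == ""
  if (!any(keep)) .stopf("all cells removed by QC")
  report <- data.frame(cell_id = colnames(counts), n_genes = n_genes,
                       mito_fraction = mito, hb_fraction = hb,
                       kept = keep, reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  out <- counts[, keep, drop = FALSE]
  if (filter_genes) {
    gk <- rowSums(out > 0) >= min_cells_per_gene
    out <- out[gk, , drop = FALSE]
  }
  list(counts = expr_matrix(out, "counts"), report = report)
}

# order annotation by (chrom, start); drop chromosomes with < min_genes
.order_annotation <- function(ann, genes, min_genes_per_chrom = 10) {
  ann <- ann[ann$gene_id %in% genes, , drop = FALSE]
  tab <- table(ann$chrom)
  bad <- names(tab)[tab < min_genes_per_chrom]
  if (length(bad)) {
    .warnf("excluding chromosome(s) with < %d annotated genes: %s",
           min_genes_per_chrom, paste(bad, collapse = ", "))
    ann <- ann[!ann$chrom %in% bad, , drop = FALSE]
  }
  ann[order(ann$chrom, ann$start, ann$gene_id, method = "radix"), , drop = FALSE]
}

# centered running mean over positions i-h1..i+h2 (h1 = floor((w-1)/2),
# h2 = w-1-h1), truncated at the ends (minimum one observation)
.running_mean <- function(m, w) {
  n <- ncol(m)
  h1 <- (w - 1L) %/% 2L; h2 <- w - 1L - h1
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(seq_len(n) - h1, 1L); hi <- pmin(seq_len(n) + h2, n)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    matrix(hi - lo + 1L, nrow(m), n, byrow = TRUE)
}

#' Reference-anchored sliding-window CNV profile
#'
#' Genes are placed in genomic order (chromosome, then start). Per gene the
#' reference-cell mean is subtracted, residuals are clamped to
#' `± clamp`, and a centered running mean over `window` genes is taken
#' within each chromosome (windows truncated at chromosome ends, minimum one
#' gene). The per-cell CNV score is the mean squared smoothed deviation.
#'
#' @param expr genes x cells log-normalized [expr_matrix()].
#' @param annotation a [genome_annotation()]; chromosomes with fewer than 10
#'   annotated genes are excluded with a warning.
#' @param reference_cells ids of non-malignant reference cells (non-empty).
#' @param window sliding-window width in genes (default 100).
#' @param clamp residual clamp before smoothing (default 3).
#' @return object of class `cnv_profile`: `smoothed` (cells x genes in
#'   genomic order), `cnv_score` (per cell), `gene_order`, `reference_cells`,
#'   `window`.
#' @export
infer_cnv_profile <- function(expr, annotation, reference_cells,
                              window = 100, clamp = 3) {
  if (!length(reference_cells)) .stopf("empty reference cell set")
  if (!all(reference_cells %in% colnames(expr)))
    .stopf("reference cells missing from the expression matrix")
  ann <- .order_annotation(annotation, rownames(expr))
  if (!nrow(ann)) .stopf("no annotated genes shared with the expression matrix")
  x <- t(expr[ann$gene_id, , drop = FALSE])      # cells x genes
  ref_mean <- colMeans(x[reference_cells, , drop = FALSE])
  resid <- sweep(x, 2, ref_mean)
  resid[resid > clamp] <- clamp
  resid[resid < -clamp] <- -clamp
  smoothed <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    smoothed[, idx] <- .running_mean(resid[, idx, drop = FALSE], window)
  }
  structure(list(smoothed = smoothed,
                 cnv_score = rowMeans(smoothed^2),
                 gene_order = ann, reference_cells = reference_cells,
                 window = window, clamp = clamp),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("cnv_profile: %d cells x %d genes (window %d); mean score %.4g\n",
              nrow(x$smoothed), ncol(x$smoothed), x$window, mean(x$cnv_score)))
  invisible(x)
}

#' Robust-Z focal event calls at driver genes
#'
#' Per driver gene, the reference cells' smoothed values give a median and a
#' 1.4826-scaled median absolute deviation (floored at `epsilon`); each
#' cell's robust Z is thresholded into gain (`Z >= z_gain`), loss
#' (`Z <= -z_loss`) or neutral.
#'
#' @param profile a `cnv_profile`.
#' @param driver_genes gene ids to call (absent genes are reported missing,
#'   not fatal).
#' @param z_gain,z_loss thresholds in robust SD units (default 2).
#' @param epsilon MAD floor (default 1e-6).
#' @return object of class `focal_calls`: `z` and `call` (cells x drivers),
#'   `missing`, thresholds.
#' @export
call_focal_events <- function(profile, driver_genes, z_gain = 2, z_loss = 2,
                              epsilon = 1e-6) {
  present <- intersect(driver_genes, colnames(profile$smoothed))
  missing <- setdiff(driver_genes, present)
  if (length(missing))
    .warnf("driver gene(s) missing from profile: %s", paste(missing, collapse = ", "))
  if (!length(present)) .stopf("no driver gene present in the profile")
  vals <- profile$smoothed[, present, drop = FALSE]
  ref <- vals[profile$reference_cells, , drop = FALSE]
  med <- apply(ref, 2, stats::median)
  mad_s <- pmax(apply(ref, 2, stats::mad, constant = 1.4826), epsilon)
  z <- sweep(sweep(vals, 2, med), 2, mad_s, "/")
  call <- matrix("neutral", nrow(z), ncol(z), dimnames = dimnames(z))
  call[z >= z_gain] <- "gain"
  call[z <= -z_loss] <- "loss"
  structure(list(z = z, call = call, missing = missing,
                 z_gain = z_gain, z_loss = z_loss, epsilon = epsilon),
            class = "focal_calls")
}

#' @export
print.focal_calls <- function(x, ...) {
  cat("focal_calls per driver:\n")
  print(apply(x$call, 2, function(v) table(factor(v, c("gain", "loss", "neutral")))))
  invisible(x)
}

#' k-nearest-neighbor graph from embedding coordinates
#' @param embedding points x dimensions matrix.
#' @param k neighbors per point (default 15).
#' @return undirected igraph with one vertex per row.
#' @export
knn_graph <- function(embedding, k = 15) {
  n <- nrow(embedding)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(embedding))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(k + 1L)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (!is.null(rownames(embedding)))
    igraph::V(g)$name <- rownames(embedding)
  g
}

# default community-detection backend: seeded Leiden over modularity
.leiden_partitioner <- function(graph, resolution, seed) {
  .with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity",
      resolution = resolution, n_iterations = 5))
  })
}

#' Silhouette-guided clustering resolution selection
#'
#' Runs a resolution-parameterized community detection (default: Leiden over
#' modularity) on the supplied neighbor graph at every grid value and scores
#' each partition by the mean silhouette width on the supplied embedding
#' (Euclidean distance). Single-cluster partitions score -1. Returns the
#' argmax (ties broken toward the smallest resolution).
#'
#' @param embedding points x dimensions coordinates (>= 3 distinct points).
#' @param graph neighbor graph (igraph) over the same points; built with
#'   [knn_graph()] when NULL.
#' @param grid resolutions to scan (default 0.2 to 2.0 by 0.1).
#' @param partitioner `function(graph, resolution, seed)` returning an
#'   integer membership vector; injectable for testing.
#' @param seed RNG seed.
#' @return object of class `clustering_solution`: `resolution` (chosen),
#'   `membership` (at the chosen resolution), `grid`, `silhouette` per grid
#'   value, `n_clusters` per grid value.
#' @export
select_resolution <- function(embedding, graph = NULL,
                              grid = seq(0.2, 2.0, by = 0.1),
                              partitioner = NULL, seed = 1) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < 3) .stopf("need at least 3 points")
  if (!length(grid)) .stopf("empty resolution grid")
  if (nrow(unique(embedding)) == 1) .stopf("all points identical in the embedding")
  if (is.null(graph)) graph <- knn_graph(embedding)
  if (is.null(partitioner)) partitioner <- .leiden_partitioner
  d <- stats::dist(embedding)
  sil <- numeric(length(grid)); memb <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    m <- as.integer(partitioner(graph, grid[i], seed))
    memb[[i]] <- stats::setNames(m, rownames(embedding))
    sil[i] <- if (length(unique(m)) < 2) -1 else
      mean(cluster::silhouette(m, d)[, "sil_width"])
  }
  best <- which.max(sil)   # which.max takes the first maximum: smallest resolution
  structure(list(resolution = grid[best], membership = memb[[best]],
                 grid = grid, silhouette = sil,
                 n_clusters = vapply(memb, function(m) length(unique(m)), integer(1)),
                 seed = seed),
            class = "clustering_solution")
}

#' @export
print.clustering_solution <- function(x, ...) {
  cat(sprintf("clustering_solution: resolution %.2f, %d clusters, silhouette %.3f\n",
              x$resolution, length(unique(x$membership)),
              max(x$silhouette)))
  invisible(x)
}

#' Tumor-like / normal-like labeling of CNV clusters
#'
#' Reference cells are labeled `"reference"`. A cluster of query cells is
#' tumor-like when its mean CNV score exceeds the reference mean by at least
#' `score_z` reference standard deviations, or when at least
#' `driver_fraction` of its cells carry any non-neutral focal driver call.
#'
#' @param profile a `cnv_profile`.
#' @param clusters a `clustering_solution` (or named membership vector)
#'   covering all non-reference cells.
#' @param calls a `focal_calls`.
#' @param score_z CNV-score threshold in reference SDs (default 2).
#' @param driver_fraction driver-call fraction threshold (default 0.3).
#' @return object of class `malignancy_labels`: `labels` (per cell),
#'   `cluster_evidence` (per cluster mean score, driver fraction, verdict).
#' @export
label_malignant <- function(profile, clusters, calls, score_z = 2,
                            driver_fraction = 0.3) {
  memb <- if (inherits(clusters, "clustering_solution")) clusters$membership else clusters
  cells <- rownames(profile$smoothed)
  ref <- profile$reference_cells
  query <- setdiff(cells, ref)
  if (!length(memb)) .stopf("no clusters supplied")
  if (!all(query %in% names(memb)))
    .stopf("clusters must cover all non-reference cells")
  ref_mu <- mean(profile$cnv_score[ref])
  ref_sd <- stats::sd(profile$cnv_score[ref])
  any_event <- rowSums(calls$call != "neutral") > 0
  labels <- stats::setNames(rep("normal-like", length(cells)), cells)
  labels[ref] <- "reference"
  ev <- do.call(rbind, lapply(sort(unique(memb[query])), function(cl) {
    cs <- intersect(names(memb)[memb == cl], query)
    mean_score <- mean(profile$cnv_score[cs])
    frac <- mean(any_event[cs])
    tumor <- mean_score >= ref_mu + score_z * ref_sd || frac >= driver_fraction
    data.frame(cluster = cl, n = length(cs), mean_cnv_score = mean_score,
               driver_call_fraction = frac, tumor_like = tumor)
  }))
  for (i in seq_len(nrow(ev)))
    if (ev$tumor_like[i]) {
      cs <- intersect(names(memb)[memb == ev$cluster[i]], query)
      labels[cs] <- "tumor-like"
    }
  structure(list(labels = labels, cluster_evidence = ev,
                 score_z = score_z, driver_fraction = driver_fraction),
            class = "malignancy_labels")
}

#' @export
print.malignancy_labels <- function(x, ...) {
  print(table(x$labels))
  invisible(x)
}
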