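# Permutation ligand-receptor scoring between annotated cell groups, the
# composite receptor-to-TF axis score, strand-aware promoter extraction and
# PWM motif scanning with exact null p-values.

#' Permutation test for ligand-receptor interaction between cell groups
#'
#' Observed score = mean ligand expression in the sender group times mean
#' receptor expression in the receiver group. The null permutes group labels
#' across all cells; p uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`. A pair is
#' significant when `p < 0.05` and the ligand's sender-vs-rest log2 fold
#' change exceeds 1.
#'
#' @param expr genes x cells matrix.
#' @param cell_groups per-cell group labels (aligned to columns).
#' @param lr_pairs data.frame with columns `ligand`, `receptor`; pairs with
#'   missing genes are skipped with a warning.
#' @param sender,receiver group labels (non-empty groups).
#' @param n_permutations default 1000.
#' @param pseudocount added to means in the fold-change ratio (default 1).
#' @param seed RNG seed.
#' @return object of class `lr_score_table`: data.frame with ligand,
#'   receptor, score, p, ligand_log2fc, significant.
#' @export
lr_permutation_test <- function(expr, cell_groups, lr_pairs, sender, receiver,
                                n_permutations = 1000, pseudocount = 1,
                                seed = 1) {
  if (n_permutations < 1) .stopf("n_permutations must be >= 1")
  if (!any(cell_groups == sender)) .stopf("empty sender group '%s'", sender)
  if (!any(cell_groups == receiver)) .stopf("empty receiver group '%s'", receiver)
  present <- lr_pairs$ligand %in% rownames(expr) &
    lr_pairs$receptor %in% rownames(expr)
  if (!all(present)) {
    .warnf("%d pair(s) skipped: gene(s) absent", sum(!present))
    lr_pairs <- lr_pairs[present, , drop = FALSE]
  }
  if (!nrow(lr_pairs)) .stopf("no scorable ligand-receptor pair")
  s_cells <- cell_groups == sender
  r_cells <- cell_groups == receiver
  lig <- expr[lr_pairs$ligand, , drop = FALSE]
  rec <- expr[lr_pairs$receptor, , drop = FALSE]
  obs <- rowMeans(lig[, s_cells, drop = FALSE]) *
    rowMeans(rec[, r_cells, drop = FALSE])
  lfc <- log2((rowMeans(lig[, s_cells, drop = FALSE]) + pseudocount) /
              (rowMeans(lig[, !s_cells, drop = FALSE]) + pseudocount))
  ge <- integer(nrow(lr_pairs))
  .with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample(cell_groups)
      ps <- perm == sender; pr <- perm == receiver
      null_s <- rowMeans(lig[, ps, drop = FALSE]) *
        rowMeans(rec[, pr, drop = FALSE])
      ge <- ge + (null_s >= obs)
    }
  })
  p <- (1 + ge) / (1 + n_permutations)
  tab <- data.frame(ligand = lr_pairs$ligand, receptor = lr_pairs$receptor,
                    score = unname(obs), p = unname(p),
                    ligand_log2fc = unname(lfc),
                    significant = unname(p < 0.05 & lfc > 1),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, sender = sender, receiver = receiver,
                 n_permutations = n_permutations),
            class = "lr_score_table")
}

#' @export
print.lr_score_table <- function(x, ...) {
  cat(sprintf("lr_score_table %s -> %s (%d permutations):\n",
              x$sender, x$receiver, x$n_permutations))
  print(x$table, digits = 3)
  invisible(x)
}

#' Composite receptor-to-TF axis score
#'
#' Per cell, the mean of per-gene min-max-scaled expression over the
#' available axis genes. Absent genes are dropped and recorded; genes with a
#' degenerate (constant) range are likewise dropped.
#'
#' @param expr genes x cells matrix.
#' @param axis_genes ordered gene list (receptor genes then the TF).
#' @return object of class `axis_score`: `score` (named, in \[0,1\]),
#'   `genes_used`, `genes_dropped`.
#' @export
axis_score <- function(expr, axis_genes) {
  present <- intersect(axis_genes, rownames(expr))
  if (!length(present)) .stopf("no axis gene present in the matrix")
  x <- expr[present, , drop = FALSE]
  rng <- apply(x, 1, function(v) diff(range(v)))
  degen <- present[rng == 0]
  used <- setdiff(present, degen)
  if (!length(used)) .stopf("all present axis genes have degenerate ranges")
  x <- x[used, , drop = FALSE]
  scaled <- (x - apply(x, 1, min)) / apply(x, 1, function(v) diff(range(v)))
  structure(list(score = colMeans(scaled), genes_used = used,
                 genes_dropped = c(setdiff(axis_genes, present), degen)),
            class = "axis_score")
}

#' @export
print.axis_score <- function(x, ...) {
  cat(sprintf("axis_score over %d genes (%d dropped); mean %.3f\n",
              length(x$genes_used), length(x$genes_dropped), mean(x$score)))
  invisible(x)
}

.revcomp <- function(s) chartr("ACGTN", "TGCAN", vapply(
  strsplit(s, ""), function(v) paste(rev(v), collapse = ""), character(1)))

#' Extract strand-aware promoter windows
#'
#' Plus-strand genes: `[TSS - upstream, TSS + downstream)` with TSS = start.
#' Minus-strand genes: `[TSS - downstream, TSS + upstream)` with TSS = end,
#' reverse-complemented. Windows are truncated at contig bounds; genes on
#' missing contigs are skipped with a warning. Coordinates are 0-based
#' half-open.
#'
#' @param annotation a [genome_annotation()].
#' @param genome named character vector of contig sequences.
#' @param upstream,downstream window extents in bp (defaults 1000 / 100).
#' @return object of class `promoter_set`: `seqs` (named by gene) and
#'   `coords` (gene, chrom, start, end, strand).
#' @export
extract_promoters <- function(annotation, genome, upstream = 1000,
                              downstream = 100) {
  missing <- setdiff(unique(annotation$chrom), names(genome))
  if (length(missing))
    .warnf("skipping genes on missing contig(s): %s",
           paste(missing, collapse = ", "))
  ann <- annotation[annotation$chrom %in% names(genome), , drop = FALSE]
  seqs <- character(0); coords <- NULL
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    clen <- nchar(genome[[g$chrom]])
    if (g$strand == "+") {
      tss <- g$start
      from <- max(0L, tss - upstream); to <- min(clen, tss + downstream)
    } else {
      tss <- g$end
      from <- max(0L, tss - downstream); to <- min(clen, tss + upstream)
    }
    if (to <= from) next
    s <- substr(genome[[g$chrom]], from + 1L, to)
    if (g$strand == "-") s <- .revcomp(s)
    seqs[[g$gene_id]] <- s
    coords <- rbind(coords, data.frame(gene = g$gene_id, chrom = g$chrom,
                                       start = from, end = to,
                                       strand = g$strand,
                                       stringsAsFactors = FALSE))
  }
  structure(list(seqs = seqs, coords = coords, upstream = upstream,
                 downstream = downstream),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters (window -%d/+%d)\n",
              length(x$seqs), x$upstream, x$downstream))
  invisible(x)
}

# integerized per-position log-odds scores and the exact null distribution
# of the total under the background model (dynamic programming convolution)
.pwm_score_dp <- function(probs, background, scale = 1000, floor_p = 1e-6) {
  w <- ncol(probs)
  lo <- log2(pmax(probs, floor_p) / background)   # 4 x w, bits
  ints <- round(lo * scale)
  # DP over offsets relative to running minimum to keep vectors small
  dist <- c(1)                                    # P(sum = offset + min)
  offset <- 0L
  for (j in seq_len(w)) {
    vals <- ints[, j]
    lo_j <- min(vals)
    span <- max(vals) - lo_j
    new <- numeric(length(dist) + span)
    for (b in 1:4)
      new[seq_along(dist) + (vals[b] - lo_j)] <-
        new[seq_along(dist) + (vals[b] - lo_j)] + dist * background[b]
    dist <- new
    offset <- offset + lo_j
  }
  support <- offset + seq_along(dist) - 1L
  tail <- rev(cumsum(rev(dist)))                  # P(score >= support[i])
  list(ints = ints, support = support, tail = tail, scale = scale)
}

# smallest integer score whose tail probability is below p
.pwm_threshold <- function(dp, p) {
  idx <- which(dp$tail < p)
  if (!length(idx)) Inf else dp$support[idx[1]]
}

.pwm_tail_at <- function(dp, s) {
  idx <- which(dp$support >= s)
  if (!length(idx)) 0 else dp$tail[idx[1]]
}

#' Scan promoters with position weight matrices (exact p-values)
#'
#' Scores every window on both strands with the log2 PWM/background
#' log-odds; p-values come from the exact null score distribution computed
#' by dynamic programming over integerized scores (scale 1000) under the
#' background model. `N` bases contribute 0 (background). A window is a hit
#' when `P(score >= s | background) < p_threshold`.
#'
#' @param promoters a `promoter_set` (or named character vector of
#'   sequences). Sequences shorter than the motif yield zero hits.
#' @param pwms list of `pwm` objects.
#' @param background base frequencies A,C,G,T (default uniform; must sum
#'   to 1).
#' @param p_threshold hit threshold on the exact p-value (default 0.01).
#' @return object of class `motif_hits`: data.frame with gene, motif_id,
#'   offset (0-based, on the given sequence), strand, score (bits), p.
#' @export
scan_motifs <- function(promoters, pwms, background = rep(0.25, 4),
                        p_threshold = 0.01) {
  seqs <- if (inherits(promoters, "promoter_set")) promoters$seqs else promoters
  if (abs(sum(background) - 1) > 1e-6)
    .stopf("background frequencies must sum to 1")
  background <- stats::setNames(as.numeric(background), c("A", "C", "G", "T"))
  hits <- NULL
  base_idx <- stats::setNames(1:4, c("A", "C", "G", "T"))
  for (pw in pwms) {
    w <- ncol(pw$probs)
    rc <- pw$probs[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
    rownames(rc) <- c("A", "C", "G", "T")
    strands <- list(`+` = .pwm_score_dp(pw$probs, background),
                    `-` = .pwm_score_dp(rc, background))
    thr <- lapply(strands, .pwm_threshold, p = p_threshold)
    for (nm in names(seqs)) {
      chars <- strsplit(seqs[[nm]], "")[[1]]
      L <- length(chars)
      if (L < w) next
      idx <- unname(base_idx[chars])          # NA for N and other letters
      n_off <- L - w + 1L
      for (st in c("+", "-")) {
        dp <- strands[[st]]
        sc <- numeric(n_off)
        for (j in seq_len(w)) {
          v <- dp$ints[cbind(idx[seq_len(n_off) + j - 1L], j)]
          v[is.na(v)] <- 0
          sc <- sc + v
        }
        hot <- which(sc >= thr[[st]])
        if (length(hot))
          hits <- rbind(hits, data.frame(
            gene = nm, motif_id = pw$motif_id, offset = hot - 1L, strand = st,
            score = sc[hot] / dp$scale,
            p = vapply(sc[hot], function(s) .pwm_tail_at(dp, s), numeric(1)),
            stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(hits))
    hits <- data.frame(gene = character(), motif_id = character(),
                       offset = integer(), strand = character(),
                       score = numeric(), p = numeric(),
                       stringsAsFactors = FALSE)
  structure(list(table = hits, p_threshold = p_threshold),
            class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("motif_hits: %d hits at p < %g\n", nrow(x$table), x$p_threshold))
  invisible(x)
}
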