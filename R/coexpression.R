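# WGCNA-style co-expression analysis: soft-threshold selection by the
# scale-free topology criterion, topological overlap, average-linkage module
# detection with a static tree cut, eigengene merging, and module-trait
# statistics. Expression here is in samples x genes orientation (the
# co-expression convention).

.check_samples_by_genes <- function(expr) {
  expr <- as.matrix(expr)
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0))
    .stopf("constant gene(s): %s",
           paste(utils::head(colnames(expr)[sds == 0], 5), collapse = ", "))
  expr
}

#' Soft-threshold selection by the scale-free topology criterion
#'
#' For each candidate power, builds the unsigned adjacency
#' `|cor|^beta`, computes per-gene connectivity, and fits
#' log10 p(k) against log10 k over occupied connectivity bins. The signed
#' fit index is `-sign(slope) * R^2`. The chosen power is the smallest with
#' fit >= `r2_target`; if none reaches it, the argmax is returned with a
#' warning flag.
#'
#' @param expr samples x genes numeric matrix (no constant gene).
#' @param powers candidate powers (default 1:20).
#' @param r2_target scale-free fit target (default 0.85).
#' @param n_bins connectivity histogram bins (default 10).
#' @return object of class `soft_threshold_report`: `table` (power, r2,
#'   mean_connectivity), `power` (chosen), `reached_target`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.85,
                                n_bins = 10) {
  expr <- .check_samples_by_genes(expr)
  if (ncol(expr) < 20 || nrow(expr) < 10)
    .stopf("need >= 20 genes and >= 10 samples")
  ac <- abs(stats::cor(expr))
  diag(ac) <- 0
  tab <- do.call(rbind, lapply(powers, function(b) {
    k <- colSums(ac^b)
    data.frame(power = b, r2 = .scale_free_fit(k, n_bins),
               mean_connectivity = mean(k))
  }))
  ok <- tab$power[!is.na(tab$r2) & tab$r2 >= r2_target]
  if (length(ok)) {
    power <- min(ok); reached <- TRUE
  } else {
    power <- tab$power[which.max(tab$r2)]; reached <- FALSE
    .warnf("no power reached scale-free fit %.2f; using argmax (power %d)",
           r2_target, power)
  }
  structure(list(table = tab, power = power, reached_target = reached,
                 r2_target = r2_target),
            class = "soft_threshold_report")
}

.scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 5) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 5) return(NA_real_)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' @export
print.soft_threshold_report <- function(x, ...) {
  cat(sprintf("soft_threshold_report: power %d (fit %s target %.2f)\n",
              x$power, if (x$reached_target) "reached" else "below", x$r2_target))
  invisible(x)
}

# unsigned topological overlap matrix from an adjacency with zero diagonal
.tom_similarity <- function(a) {
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

.module_eigengene <- function(expr_members) {
  z <- scale(expr_members)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x[, 1]
  if (mean(stats::cor(pc, z)) < 0) pc <- -pc   # orient: mean member cor > 0
  pc
}

#' Detect co-expression modules by topological overlap
#'
#' Builds the unsigned TOM at the given power, clusters genes by
#' average-linkage on TOM dissimilarity, cuts the tree statically at
#' `cut_height`, sends branches smaller than `min_module_size` to grey, and
#' iteratively merges module pairs whose eigengenes correlate above
#' `1 - merge_cut_height`.
#'
#' @param expr samples x genes matrix.
#' @param power soft-threshold power (from [pick_soft_threshold()]).
#' @param min_module_size smallest retained module (default 30).
#' @param merge_cut_height eigengene-dissimilarity merge threshold
#'   (default 0.25).
#' @param cut_height static tree-cut height on TOM dissimilarity
#'   (default 0.99).
#' @return object of class `module_set`: `labels` (per gene, `"grey"` =
#'   unassigned), `eigengenes` (samples x modules), parameters.
#' @export
detect_modules <- function(expr, power, min_module_size = 30,
                           merge_cut_height = 0.25, cut_height = 0.99) {
  stopifnot(power >= 1)
  expr <- .check_samples_by_genes(expr)
  genes <- colnames(expr)
  if (ncol(expr) < min_module_size) {
    .warnf("fewer genes than min_module_size; all grey")
    return(structure(list(
      labels = stats::setNames(rep("grey", ncol(expr)), genes),
      eigengenes = NULL, power = power,
      min_module_size = min_module_size,
      merge_cut_height = merge_cut_height), class = "module_set"))
  }
  a <- abs(stats::cor(expr))^power
  diag(a) <- 0
  tom <- .tom_similarity(a)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- stats::setNames(rep("grey", length(genes)), genes)
  for (i in seq_along(keep))
    labels[raw == as.integer(keep[i])] <- paste0("M", i)
  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    me <- sapply(mods, function(m)
      .module_eigengene(expr[, labels == m, drop = FALSE]))
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= 1 - merge_cut_height) break
    labels[labels == mods[mx[2]]] <- mods[mx[1]]
  }
  mods <- setdiff(unique(labels), "grey")
  # relabel by decreasing size for stable naming
  mods <- mods[order(-vapply(mods, function(m) sum(labels == m), integer(1)))]
  relab <- stats::setNames(paste0("M", seq_along(mods)), mods)
  labels[labels != "grey"] <- relab[labels[labels != "grey"]]
  mods <- unname(relab)
  me <- if (length(mods))
    sapply(mods, function(m) .module_eigengene(expr[, labels == m, drop = FALSE]))
  else NULL
  if (!is.null(me)) rownames(me) <- rownames(expr)
  structure(list(labels = labels, eigengenes = me, power = power,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  print(table(x$labels))
  invisible(x)
}

#' Module-trait correlations, module membership (kME) and gene significance
#'
#' @param modules a `module_set`.
#' @param expr samples x genes matrix (the one modules were detected on).
#' @param traits named list or data.frame of per-sample numeric traits.
#' @return object of class `module_trait_stats`: `module_trait` (module,
#'   trait, cor, p), `kme` (per gene, own-module eigengene correlation),
#'   `gs` (genes x traits correlations).
#' @export
module_trait_stats <- function(modules, expr, traits) {
  expr <- as.matrix(expr)
  traits <- as.data.frame(traits)
  if (nrow(traits) != nrow(expr)) .stopf("traits not aligned to samples")
  me <- modules$eigengenes
  if (is.null(me)) .stopf("module set has no non-grey modules")
  cor_p <- function(x, y) {
    if (stats::sd(y) == 0 || stats::sd(x) == 0) return(c(NA_real_, NA_real_))
    r <- stats::cor(x, y)
    n <- length(x)
    t <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    c(r, 2 * stats::pt(-abs(t), n - 2))
  }
  mt <- do.call(rbind, lapply(colnames(me), function(m)
    do.call(rbind, lapply(names(traits), function(tr) {
      rp <- cor_p(me[, m], traits[[tr]])
      data.frame(module = m, trait = tr, cor = rp[1], p = rp[2])
    }))))
  kme <- stats::setNames(rep(NA_real_, ncol(expr)), colnames(expr))
  for (m in colnames(me)) {
    members <- names(modules$labels)[modules$labels == m]
    kme[members] <- drop(stats::cor(expr[, members, drop = FALSE], me[, m]))
  }
  gs <- sapply(names(traits), function(tr) {
    if (stats::sd(traits[[tr]]) == 0) return(rep(NA_real_, ncol(expr)))
    drop(stats::cor(expr, traits[[tr]]))
  })
  rownames(gs) <- colnames(expr)
  structure(list(module_trait = mt, kme = kme, gs = gs),
            class = "module_trait_stats")
}

#' @export
print.module_trait_stats <- function(x, ...) {
  print(x$module_trait, digits = 3)
  invisible(x)
}
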