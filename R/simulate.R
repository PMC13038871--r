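# Synthetic cohort generators with planted, recoverable ground truth.
# Every generator is a pure function of its config (seed included); the
# planted elements are returned as a `ground_truth` record that round-trips
# through JSON.

#' Configuration for a synthetic bulk survival cohort
#'
#' Expression is generated as pathway latent activity (standard normal per
#' sample) mapped onto member genes plus log-scale noise; survival times
#' follow an exponential proportional-hazards model whose linear predictor is
#' the weighted sum of planted pathway activities.
#'
#' @param n_samples,n_genes,n_pathways,genes_per_pathway cohort dimensions.
#' @param planted_pathways named numeric: log hazard ratio per unit activity
#'   for each planted pathway, names are pathway indices (`"3"`) or pathway
#'   names (`"PW3"`).
#' @param baseline_hazard exponential baseline event rate per day.
#' @param censoring_rate target fraction of censored subjects (independent
#'   exponential censoring, rate calibrated numerically).
#' @param noise_sd residual gene-level SD on the log2 scale.
#' @param seed RNG seed.
#' @export
bulk_sim_config <- function(n_samples = 300, n_genes = 1000, n_pathways = 50,
                            genes_per_pathway = 20,
                            planted_pathways = c("1" = 0.8),
                            baseline_hazard = 1 / 730,
                            censoring_rate = 0.3, noise_sd = 1, seed = 1) {
  stopifnot(n_samples > 0, n_genes > 0, n_pathways > 0, genes_per_pathway > 0,
            censoring_rate >= 0, censoring_rate < 1,
            all(is.finite(planted_pathways)))
  structure(as.list(environment()), class = "bulk_sim_config")
}

#' Simulate a bulk expression cohort with planted prognostic pathways
#'
#' @param config a [bulk_sim_config()].
#' @return list with `expr` (genes x samples [expr_matrix()], log2 scale),
#'   `surv` ([survival_table()]), `sets` (gene_set_collection mapping each
#'   pathway to its member genes), and `truth` (a `ground_truth` record).
#' @export
simulate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  cfg <- config
  pw_names <- sprintf("PW%d", seq_len(cfg$n_pathways))
  idx <- names(cfg$planted_pathways)
  planted_idx <- ifelse(idx %in% pw_names, match(idx, pw_names),
                        suppressWarnings(as.integer(idx)))
  if (any(is.na(planted_idx)) || any(planted_idx < 1) ||
      any(planted_idx > cfg$n_pathways))
    .stopf("planted pathway index out of range 1..%d", cfg$n_pathways)
  theta <- stats::setNames(as.numeric(cfg$planted_pathways), pw_names[planted_idx])

  .with_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    samples <- sprintf("S%04d", seq_len(cfg$n_samples))
    # pathway memberships: consecutive, non-overlapping while genes last
    members <- lapply(seq_len(cfg$n_pathways), function(p) {
      i <- ((p - 1L) * cfg$genes_per_pathway) %% cfg$n_genes
      genes[(i + seq_len(cfg$genes_per_pathway) - 1L) %% cfg$n_genes + 1L]
    })
    names(members) <- pw_names
    activity <- matrix(stats::rnorm(cfg$n_pathways * cfg$n_samples),
                       cfg$n_pathways, cfg$n_samples,
                       dimnames = list(pw_names, samples))
    expr <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, 5, cfg$noise_sd),
                   cfg$n_genes, cfg$n_samples,
                   dimnames = list(genes, samples))
    for (p in seq_len(cfg$n_pathways))
      expr[members[[p]], ] <- expr[members[[p]], ] +
        matrix(activity[p, ], length(members[[p]]), cfg$n_samples, byrow = TRUE)

    eta <- drop(crossprod(activity[names(theta), , drop = FALSE], theta))
    rate <- cfg$baseline_hazard * exp(eta)
    t_event <- stats::rexp(cfg$n_samples, rate)
    if (cfg$censoring_rate > 0) {
      # calibrate independent exponential censoring to the target fraction:
      # P(censored) = mean_i rc / (rc + rate_i)
      f <- function(rc) mean(rc / (rc + rate)) - cfg$censoring_rate
      rc <- stats::uniroot(f, c(1e-12, 1e6 * max(rate)))$root
      t_cens <- stats::rexp(cfg$n_samples, rc)
    } else t_cens <- rep(Inf, cfg$n_samples)
    time <- pmax(pmin(t_event, t_cens), 0.5)
    surv <- survival_table(data.frame(
      subject_id = samples, time = time,
      event = as.integer(t_event <= t_cens)))

    sets <- structure(lapply(pw_names, function(p)
      list(description = "synthetic pathway", genes = members[[p]])),
      names = pw_names, class = "gene_set_collection")
    truth <- structure(list(
      kind = "bulk_cohort",
      planted_pathways = as.list(theta),
      latent_activity = activity,
      n_samples = cfg$n_samples, seed = cfg$seed), class = "ground_truth")
    list(expr = expr_matrix(expr, "continuous"), surv = surv,
         sets = sets, truth = truth)
  })
}

#' Configuration for a synthetic single-cell dataset
#'
#' Negative-binomial counts with per-cell-type mean profiles; malignant cells
#' additionally carry contiguous CNV gain/loss blocks (block means multiplied
#' by a fold-change), planted DE shifts, a latent pseudotime in \[0,1\] with
#' trend genes, and elevated ligand/receptor genes in sender/receiver types.
#'
#' @param n_cells named integer vector, cells per cell type.
#' @param reference_types cell types forming the non-malignant CNV reference.
#' @param malignant_type the designated malignant type (disjoint from
#'   reference).
#' @param n_genes number of genes, laid out in genomic order.
#' @param genes_per_chrom genes per synthetic chromosome.
#' @param cnv_blocks list of `list(from =, to =, fold =)` gene-index ranges.
#' @param de_genes named numeric log2 fold changes (malignant vs rest).
#' @param pseudotime_genes named character: `"late_up"`, `"early_peak"` or
#'   `"down"` per planted trend gene.
#' @param lr_pairs data.frame with columns ligand, receptor, sender,
#'   receiver, strength (mean fold elevation).
#' @param dispersion NB dispersion (1/size); shared across genes.
#' @param lib_size mean library-scale factor.
#' @param seed RNG seed.
#' @export
sc_sim_config <- function(n_cells = c(Tcell = 200, Bcell = 100, Ductal = 200),
                          reference_types = c("Tcell", "Bcell"),
                          malignant_type = "Ductal",
                          n_genes = 1000, genes_per_chrom = 500,
                          cnv_blocks = list(), de_genes = numeric(),
                          pseudotime_genes = character(),
                          lr_pairs = NULL,
                          dispersion = 0.1, lib_size = 1, seed = 1) {
  stopifnot(length(n_cells) >= 1, all(n_cells >= 1), !is.null(names(n_cells)),
            n_genes >= 1, dispersion > 0)
  if (any(n_cells < 1)) .stopf("empty cell type")
  if (malignant_type %in% reference_types)
    .stopf("malignant type must be disjoint from reference types")
  if (!all(c(reference_types, malignant_type) %in% names(n_cells)))
    .stopf("reference/malignant types must appear in n_cells")
  for (b in cnv_blocks) {
    if (b$from < 1 || b$to > n_genes || b$from > b$to)
      .stopf("CNV block range outside 1..%d", n_genes)
    if (b$fold <= 0) .stopf("CNV fold-change must be positive")
  }
  structure(as.list(environment()), class = "sc_sim_config")
}

.trend_multiplier <- function(trend, u, amp = 2) {
  s <- switch(trend,
    late_up   = 1 / (1 + exp(-(u - 0.6) / 0.08)),
    down      = 1 / (1 + exp((u - 0.4) / 0.08)),
    early_peak = exp(-((u - 0.3)^2) / (2 * 0.12^2)),
    .stopf("unknown trend '%s'", trend))
  2^(amp * s)
}

#' Simulate a single-cell count dataset with planted CNV, DE and trends
#'
#' @param config an [sc_sim_config()].
#' @return list with `counts` (genes x cells [expr_matrix()], counts mode),
#'   `meta` (cell_id, cell_type, is_malignant, is_reference, pseudotime),
#'   `annotation` ([genome_annotation()]) and `truth`.
#' @export
simulate_sc_dataset <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  cfg <- config
  .with_seed(cfg$seed, {
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    n_chrom <- ceiling(cfg$n_genes / cfg$genes_per_chrom)
    chrom <- sprintf("chr%d", rep(seq_len(n_chrom), each = cfg$genes_per_chrom))[seq_len(cfg$n_genes)]
    pos_in <- (seq_len(cfg$n_genes) - 1L) %% cfg$genes_per_chrom
    ann <- genome_annotation(data.frame(
      gene_id = genes, chrom = chrom,
      start = pos_in * 10000L, end = pos_in * 10000L + 2000L,
      strand = rep_len(c("+", "-"), cfg$n_genes), stringsAsFactors = FALSE))

    types <- names(cfg$n_cells)
    cell_type <- rep(types, times = cfg$n_cells)
    n_tot <- length(cell_type)
    cell_id <- sprintf("C%05d", seq_len(n_tot))
    is_mal <- cell_type == cfg$malignant_type
    is_ref <- cell_type %in% cfg$reference_types

    # baseline gene means (log-normal) + per-type marker elevation so that
    # types separate in expression space
    base_mu <- exp(stats::rnorm(cfg$n_genes, log(2), 0.8))
    type_mu <- sapply(types, function(tp) {
      mu <- base_mu
      markers <- sample.int(cfg$n_genes, max(10L, round(0.05 * cfg$n_genes)))
      mu[markers] <- mu[markers] * 4
      mu
    })
    rownames(type_mu) <- genes

    u <- rep(NA_real_, n_tot)
    u[is_mal] <- stats::runif(sum(is_mal))

    mu <- type_mu[, cell_type, drop = FALSE]
    # planted malignant structure
    if (any(is_mal)) {
      for (b in cfg$cnv_blocks)
        mu[b$from:b$to, is_mal] <- mu[b$from:b$to, is_mal] * b$fold
      for (g in names(cfg$de_genes))
        mu[g, is_mal] <- mu[g, is_mal] * 2^cfg$de_genes[[g]]
      for (g in names(cfg$pseudotime_genes))
        mu[g, is_mal] <- mu[g, is_mal] *
          .trend_multiplier(cfg$pseudotime_genes[[g]], u[is_mal])
    }
    if (!is.null(cfg$lr_pairs)) {
      for (i in seq_len(nrow(cfg$lr_pairs))) {
        p <- cfg$lr_pairs[i, ]
        mu[p$ligand, cell_type == p$sender] <-
          mu[p$ligand, cell_type == p$sender] * p$strength
        mu[p$receptor, cell_type == p$receiver] <-
          mu[p$receptor, cell_type == p$receiver] * p$strength
      }
    }
    lib <- cfg$lib_size * exp(stats::rnorm(n_tot, 0, 0.2))
    mu <- sweep(mu, 2, lib, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     cfg$n_genes, n_tot, dimnames = list(genes, cell_id))

    meta <- data.frame(cell_id = cell_id, cell_type = cell_type,
                       is_malignant = is_mal, is_reference = is_ref,
                       pseudotime = u, stringsAsFactors = FALSE)
    truth <- structure(list(
      kind = "sc_dataset",
      cnv_blocks = cfg$cnv_blocks,
      de_genes = as.list(cfg$de_genes),
      pseudotime_genes = as.list(cfg$pseudotime_genes),
      lr_pairs = cfg$lr_pairs,
      malignant_cells = cell_id[is_mal],
      reference_cells = cell_id[is_ref],
      seed = cfg$seed), class = "ground_truth")
    list(counts = expr_matrix(counts, "counts"), meta = meta,
         annotation = ann, truth = truth)
  })
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Backgrounds are i.i.d. uniform over A,C,G,T; a `planted_fraction` of the
#' sequences receive one motif instance sampled from the PWM columns at a
#' uniformly drawn, recorded offset.
#'
#' @param n_sequences number of promoters.
#' @param length sequence length (>= motif width).
#' @param motif a `pwm`.
#' @param planted_fraction fraction of sequences carrying an instance.
#' @param seed RNG seed.
#' @return list with `seqs` (named character vector) and `truth` (planted
#'   positions: sequence name, 0-based offset).
#' @export
simulate_promoters <- function(n_sequences, length, motif,
                               planted_fraction = 0.5, seed = 1) {
  stopifnot(inherits(motif, "pwm"), planted_fraction >= 0, planted_fraction <= 1)
  w <- ncol(motif$probs)
  if (length < w) .stopf("sequence length %d < motif width %d", length, w)
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    seqs <- vapply(seq_len(n_sequences), function(i)
      paste(sample(bases, length, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- sprintf("seq%04d", seq_len(n_sequences))
    n_plant <- round(planted_fraction * n_sequences)
    planted <- if (n_plant > 0) sort(sample.int(n_sequences, n_plant)) else integer()
    pos <- data.frame(sequence = character(), offset = integer(),
                      stringsAsFactors = FALSE)
    for (i in planted) {
      off <- sample.int(length - w + 1L, 1L) - 1L
      inst <- vapply(seq_len(w), function(j)
        sample(bases, 1, prob = motif$probs[, j]), character(1))
      s <- strsplit(seqs[[i]], "")[[1]]
      s[(off + 1):(off + w)] <- inst
      seqs[[i]] <- paste(s, collapse = "")
      pos <- rbind(pos, data.frame(sequence = names(seqs)[i], offset = off,
                                   stringsAsFactors = FALSE))
    }
    truth <- structure(list(kind = "promoters", motif_id = motif$motif_id,
                            planted = pos, seed = seed),
                       class = "ground_truth")
    list(seqs = seqs, truth = truth)
  })
}

#' Serialize / restore a ground-truth record as JSON
#' @param truth a `ground_truth`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$latent_activity <- NULL   # large nuisance matrix; planted elements suffice
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE),
            class = "ground_truth")
}
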