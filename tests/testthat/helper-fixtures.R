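# Shared fixtures and independent mini-oracles used across test files.

toy_surv <- function(time, event, ids = sprintf("S%02d", seq_along(time))) {
  survival_table(data.frame(subject_id = ids, time = time, event = event))
}

toy_expr <- function(values, genes = NULL, samples = NULL,
                     mode = "continuous") {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, mode)
}

gsc <- function(...) {
  sets <- list(...)
  structure(lapply(sets, function(g) list(description = "d", genes = g)),
            class = "gene_set_collection")
}

# independent running-sum evaluation of the single-sample enrichment score
ssgsea_oracle <- function(x, set_genes, alpha) {
  ord <- names(x)[order(-x, names(x), method = "radix")]
  n <- length(x)
  inset <- ord %in% set_genes
  rank_val <- (n - seq_len(n) + 1)^alpha
  es <- 0; hit <- 0; miss <- 0
  tot_w <- sum(rank_val[inset])
  for (i in seq_len(n)) {
    if (inset[i]) hit <- hit + rank_val[i] / tot_w
    else miss <- miss + 1 / (n - sum(inset))
    es <- es + (hit - miss)
  }
  es
}

# brute-force Harrell concordance over explicit pair enumeration
cindex_oracle <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) 0.5 else num / den
}

# direct-sum IPCW cumulative/dynamic AUC with a hand-rolled censoring KM
tdauc_oracle <- function(risk, time, event, t0) {
  km_cens_left <- function(u) {
    tk <- sort(unique(time))
    g <- 1
    for (t in tk[tk < u]) {
      n_at <- sum(time >= t)
      d_c <- sum(time == t & event == 0)
      g <- g * (1 - d_c / n_at)
    }
    g
  }
  cases <- which(time <= t0 & event == 1)
  ctrls <- which(time > t0)
  if (!length(cases) || !length(ctrls)) return(NA_real_)
  w <- vapply(time[cases], km_cens_left, numeric(1))
  w <- 1 / pmax(w, 1e-12)
  num <- 0
  for (a in seq_along(cases)) for (b in ctrls) {
    conc <- if (risk[cases[a]] > risk[b]) 1
            else if (risk[cases[a]] == risk[b]) 0.5 else 0
    num <- num + w[a] * conc
  }
  num / (sum(w) * length(ctrls))
}

# log-normalize counts to a common depth, log2(1 + cpm/100)
lognorm <- function(counts, depth = 1e4) {
  x <- log2(1 + sweep(unclass(counts), 2, colSums(counts) / depth, "/"))
  expr_matrix(x, "continuous")
}

strong_pwm <- function(width = 8, consensus_p = 0.97,
                       consensus = rep("A", width)) {
  probs <- matrix((1 - consensus_p) / 3, 4, width,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(width)) probs[consensus[j], j] <- consensus_p
  pwm("strong", probs)
}
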