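test_that("ligand-receptor scoring: zero ligand, planted pair, guards", {
  set.seed(1)
  n <- 600
  groups <- rep(c("Mono", "Tumor", "Other"), each = 200)
  expr <- matrix(rexp(4 * n, 1), 4, n,
                 dimnames = list(c("LIG", "REC", "ZERO", "BG"),
                                 sprintf("C%03d", 1:n)))
  expr["LIG", groups == "Mono"] <- expr["LIG", groups == "Mono"] * 8
  expr["REC", groups == "Tumor"] <- expr["REC", groups == "Tumor"] * 8
  expr["ZERO", groups == "Mono"] <- 0
  pairs <- data.frame(ligand = c("LIG", "ZERO", "GONE"),
                      receptor = c("REC", "REC", "REC"),
                      stringsAsFactors = FALSE)
  expect_warning(res <- lr_permutation_test(expr, groups, pairs, "Mono",
                                            "Tumor", n_permutations = 1000,
                                            seed = 2), "skipped")
  tab <- res$table
  expect_equal(nrow(tab), 2)
  planted <- tab[tab$ligand == "LIG", ]
  expect_equal(planted$p, 1 / 1001)
  expect_gt(planted$ligand_log2fc, 1)
  expect_true(planted$significant)
  zero <- tab[tab$ligand == "ZERO", ]
  expect_equal(zero$score, 0)
  expect_false(zero$significant)
  expect_error(lr_permutation_test(expr, groups, pairs[1, ], "Mono", "Tumor",
                                   n_permutations = 0), ">= 1")
  expect_error(lr_permutation_test(expr, groups, pairs[1, ], "Missing",
                                   "Tumor"), "sender")
})

test_that("null ligand-receptor p-values are super-uniform", {
  set.seed(3)
  n <- 300
  groups <- rep(c("A", "B", "C"), each = 100)
  genes <- sprintf("G%02d", 1:40)
  expr <- matrix(rexp(40 * n), 40, n, dimnames = list(genes, NULL))
  colnames(expr) <- sprintf("C%03d", 1:n)
  pairs <- data.frame(ligand = genes[1:20], receptor = genes[21:40],
                      stringsAsFactors = FALSE)
  res <- lr_permutation_test(expr, groups, pairs, "A", "B",
                             n_permutations = 200, seed = 4)
  p <- res$table$p
  expect_true(all(p >= 1 / 201 & p <= 1))
  expect_lte(mean(p <= 0.1), 0.25)
  expect_gte(mean(p), 0.35)
})

test_that("axis score hits its bounds and matches hand arithmetic", {
  expr <- matrix(c(0, 1, 2, 4,    # G1 over 4 cells
                   0, 2, 6, 8,    # G2
                   1, 1, 3, 5),   # G3
                 3, 4, byrow = TRUE,
                 dimnames = list(c("G1", "G2", "G3"), sprintf("C%d", 1:4)))
  res <- axis_score(expr, c("G1", "G2", "G3"))
  # hand: scaled columns; C4 at every max -> 1; C1 at every min -> 0
  expect_equal(unname(res$score["C4"]), 1)
  expect_equal(unname(res$score["C1"]), 0)
  hand_c3 <- mean(c(2 / 4, 6 / 8, 2 / 4))
  expect_equal(unname(res$score["C3"]), hand_c3)
  # invariance to per-gene affine rescaling
  expr2 <- expr * c(2, 10, 0.5) + c(5, -3, 100)
  expect_equal(axis_score(expr2, c("G1", "G2", "G3"))$score, res$score)
  # absent and degenerate genes are dropped and recorded
  expr3 <- rbind(expr, CONST = rep(7, 4))
  res3 <- axis_score(expr3, c("G1", "G2", "G3", "CONST", "ABSENT"))
  expect_setequal(res3$genes_dropped, c("CONST", "ABSENT"))
  expect_equal(res3$score, res$score)
  expect_error(axis_score(expr, "NOPE"), "no axis gene")
})

test_that("promoter windows follow the strand-aware TSS arithmetic", {
  genome <- c(chr1 = paste(rep("ACGT", 5000), collapse = ""))
  ann <- genome_annotation(data.frame(
    gene_id = c("plus", "minus", "edge"),
    chrom = "chr1",
    start = c(10000L, 3000L, 500L),
    end = c(12000L, 5000L, 900L),
    strand = c("+", "-", "+")))
  ps <- extract_promoters(ann, genome, upstream = 1000, downstream = 100)
  co <- ps$coords
  expect_equal(co[co$gene == "plus", c("start", "end")],
               data.frame(start = 9000L, end = 10100L), ignore_attr = TRUE)
  expect_equal(nchar(ps$seqs[["plus"]]), 1100)
  # truncated at the contig start: [0, 600)
  expect_equal(co[co$gene == "edge", c("start", "end")],
               data.frame(start = 0L, end = 600L), ignore_attr = TRUE)
  # minus strand: [end - downstream, end + upstream) reverse-complemented
  expect_equal(co[co$gene == "minus", c("start", "end")],
               data.frame(start = 4900L, end = 6000L), ignore_attr = TRUE)
  win <- substr(genome[["chr1"]], 4901, 6000)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(win, "")[[1]]), collapse = ""))
  expect_equal(ps$seqs[["minus"]], rc)
})

test_that("minus-strand promoter on a tiny contig equals the hand reverse-complement", {
  genome <- c(tiny = "AAACCCGGGTTTAAACCCGGGTTTAAACCCGGGTTTAAACCCGGGTTTAA")
  ann <- genome_annotation(data.frame(
    gene_id = "g", chrom = "tiny", start = 5L, end = 30L, strand = "-"))
  ps <- extract_promoters(ann, genome, upstream = 40, downstream = 10)
  # window [30 - 10, 30 + 40) truncated to [20, 50)
  win <- substr(genome[["tiny"]], 21, 50)
  rc <- chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(win, "")[[1]]), collapse = ""))
  expect_equal(unname(ps$seqs[["g"]]), rc)
  # genes on missing contigs are skipped with a warning
  ann2 <- genome_annotation(data.frame(
    gene_id = c("g", "lost"), chrom = c("tiny", "nope"),
    start = c(5L, 1L), end = c(30L, 20L), strand = "-"))
  expect_warning(ps2 <- extract_promoters(ann2, genome), "nope")
  expect_named(ps2$seqs, "g")
})

test_that("motif DP tail probabilities equal exhaustive tetramer enumeration", {
  set.seed(7)
  probs <- matrix(rexp(16), 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  probs <- sweep(probs, 2, colSums(probs), "/")
  m <- pwm("W4", probs)
  bg <- c(0.25, 0.25, 0.25, 0.25)
  dp <- pathdriver:::.pwm_score_dp(m$probs, setNames(bg, c("A", "C", "G", "T")))
  # enumerate all 256 tetramers with the same integerized scores
  ints <- dp$ints
  words <- expand.grid(b1 = 1:4, b2 = 1:4, b3 = 1:4, b4 = 1:4)
  scores <- ints[cbind(words$b1, 1)] + ints[cbind(words$b2, 2)] +
    ints[cbind(words$b3, 3)] + ints[cbind(words$b4, 4)]
  for (s in sample(unique(scores), 10)) {
    expect_equal(pathdriver:::.pwm_tail_at(dp, s), mean(scores >= s),
                 tolerance = 1e-12)
  }
})

test_that("flat motifs and short sequences yield zero hits", {
  flat <- pwm("flat", matrix(0.25, 4, 4))
  hits <- scan_motifs(c(s1 = "ACGTACGTACGT"), list(flat))
  expect_equal(nrow(hits$table), 0)
  m <- strong_pwm(8)
  hits2 <- scan_motifs(c(s1 = "ACGT"), list(m))
  expect_equal(nrow(hits2$table), 0)
  expect_error(scan_motifs(c(s1 = "ACGT"), list(m), background = c(1, 1, 1, 1)),
               "sum to 1")
})

test_that("reported hits satisfy the p threshold and strand symmetry", {
  m <- strong_pwm(8, consensus = c("A", "C", "G", "T", "A", "C", "G", "T"))
  set.seed(8)
  sim <- simulate_promoters(30, 200, m, planted_fraction = 0.5, seed = 8)
  hits <- scan_motifs(sim$seqs, list(m), p_threshold = 0.01)
  expect_true(all(hits$table$p < 0.01))
  # scanning the reverse complements swaps strands and mirrors offsets
  rc_seqs <- vapply(sim$seqs, function(s)
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    character(1))
  hits_rc <- scan_motifs(rc_seqs, list(m), p_threshold = 0.01)
  a <- hits$table[order(hits$table$gene, hits$table$offset, hits$table$strand), ]
  b <- hits_rc$table
  b$offset <- 200 - 8 - b$offset
  b$strand <- ifelse(b$strand == "+", "-", "+")
  b <- b[order(b$gene, b$offset, b$strand), ]
  expect_equal(a$offset, b$offset)
  expect_equal(a$strand, b$strand)
  expect_equal(a$score, b$score, tolerance = 1e-12)
})

test_that("N bases score as background and do not block scanning", {
  m <- strong_pwm(4)
  hits <- scan_motifs(c(s1 = "NNAAAANN"), list(m), p_threshold = 0.05)
  expect_true("s1" %in% hits$table$gene)   # AAAA window still found
})

test_that("planted strong motifs are recovered at >= 90% at p < 0.01", {
  m <- strong_pwm(8)
  sim <- simulate_promoters(100, 500, m, planted_fraction = 0.5, seed = 1)
  hits <- scan_motifs(sim$seqs, list(m), p_threshold = 0.01)
  planted <- sim$truth$planted
  found <- mapply(function(s, o)
    any(hits$table$gene == s & hits$table$offset == o & hits$table$strand == "+"),
    planted$sequence, planted$offset)
  expect_gte(mean(found), 0.9)
  # the exact-p guarantee: false positives per scanned window stay below p
  bg_windows <- 50 * (500 - 8 + 1) * 2   # unplanted sequences, both strands
  fp <- sum(!hits$table$gene %in% planted$sequence)
  expect_lte(fp / bg_windows, 0.01)
})
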