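make_ann <- function(n, per_chrom = n) {
  genome_annotation(data.frame(
    gene_id = sprintf("G%05d", 1:n),
    chrom = sprintf("chr%d", rep(seq_len(ceiling(n / per_chrom)),
                                 each = per_chrom))[1:n],
    start = ((1:n - 1) %% per_chrom) * 1000L,
    end = ((1:n - 1) %% per_chrom) * 1000L + 500L,
    strand = "+"))
}

test_that("QC removes cells by each rule, matching a rule-by-rule oracle", {
  set.seed(1)
  n_genes <- 400
  counts <- matrix(rpois(n_genes * 10, 3), n_genes, 10,
                   dimnames = list(c("MT1", "MT2", "HBB",
                                     sprintf("G%03d", 1:(n_genes - 3))),
                                   sprintf("C%02d", 1:10)))
  counts[, 1] <- 0; counts[1:150, 1] <- 1          # 150 detected genes
  counts["MT1", 2] <- round(sum(counts[, 2]) / 2)  # mito fraction > 0.20
  counts["HBB", 3] <- round(sum(counts[, 3]) / 2)  # hemoglobin > 0.15
  em <- expr_matrix(counts, "counts")
  res <- qc_filter_cells(em, mito_genes = c("MT1", "MT2"), hb_genes = "HBB",
                         filter_genes = FALSE)
  expect_false(res$report$kept[1]); expect_equal(res$report$reason[1], "too_few_genes")
  expect_false(res$report$kept[2]); expect_equal(res$report$reason[2], "high_mito")
  expect_false(res$report$kept[3]); expect_equal(res$report$reason[3], "high_hemoglobin")
  # independent oracle: recompute every rule directly
  ng <- colSums(counts > 0)
  mito <- colSums(counts[c("MT1", "MT2"), ]) / colSums(counts)
  hb <- counts["HBB", ] / colSums(counts)
  keep <- ng >= 200 & ng <= 10000 & mito <= 0.2 & hb <= 0.15
  expect_equal(colnames(res$counts), names(keep)[keep])
})

test_that("QC gene filtering drops genes detected in < 50 cells and guards", {
  set.seed(2)
  counts <- matrix(rpois(100 * 60, 2), 100, 60,
                   dimnames = list(sprintf("G%03d", 1:100),
                                   sprintf("C%03d", 1:60)))
  counts[1, ] <- 0; counts[1, 1:10] <- 5          # detected in 10 cells only
  em <- expr_matrix(counts, "counts")
  res <- qc_filter_cells(em, thresholds = qc_thresholds(min_genes = 1))
  expect_false("G001" %in% rownames(res$counts))
  expect_error(qc_filter_cells(em, thresholds = qc_thresholds(min_genes = 5000)),
               "all cells")
})

test_that("CNV profile of a cell equal to the reference mean is exactly zero", {
  set.seed(3)
  n <- 60
  expr <- matrix(rnorm(n * 21), n, 21,
                 dimnames = list(sprintf("G%05d", 1:n), sprintf("C%02d", 1:21)))
  refs <- sprintf("C%02d", 1:20)
  expr[, 21] <- rowMeans(expr[, refs])
  prof <- infer_cnv_profile(expr_matrix(expr, "continuous"), make_ann(n),
                            refs, window = 10)
  expect_equal(max(abs(prof$smoothed["C21", ])), 0)
  expect_equal(unname(prof$cnv_score["C21"]), 0)
})

test_that("smoothing matches a direct moving-average oracle including ramps", {
  set.seed(4)
  n <- 600
  expr <- matrix(rnorm(n * 30, 0, 0.3), n, 30,
                 dimnames = list(sprintf("G%05d", 1:n), sprintf("C%02d", 1:30)))
  expr[201:500, 30] <- expr[201:500, 30] + 1      # planted gain block
  em <- expr_matrix(expr, "continuous")
  refs <- sprintf("C%02d", 1:29)
  prof <- infer_cnv_profile(em, make_ann(n), refs, window = 100)
  # independent oracle: centered mean over i-h1..i+h2 of clamped residuals
  resid <- expr - rowMeans(expr[, refs])
  resid <- pmin(pmax(resid, -3), 3)
  w <- 100; h1 <- (w - 1) %/% 2; h2 <- w - 1 - h1
  for (i in c(1, 30, 180, 350, 480, 530, 600)) {
    lo <- max(1, i - h1); hi <- min(n, i + h2)
    expect_equal(unname(prof$smoothed["C30", i]),
                 mean(resid[lo:hi, 30]), tolerance = 1e-10)
  }
  # block interior is elevated; far outside is not
  expect_gt(mean(prof$smoothed["C30", 300:400]), 0.8)
  expect_lt(abs(mean(prof$smoothed["C30", 1:100])), 0.2)
})

test_that("windows truncate when a chromosome has fewer genes than the window", {
  set.seed(5)
  n <- 50
  expr <- matrix(rnorm(n * 12), n, 12,
                 dimnames = list(sprintf("G%05d", 1:n), sprintf("C%02d", 1:12)))
  prof <- infer_cnv_profile(expr_matrix(expr, "continuous"), make_ann(n),
                            sprintf("C%02d", 1:10), window = 100)
  expect_equal(ncol(prof$smoothed), 50)
  expect_true(all(is.finite(prof$smoothed)))
})

test_that("CNV profile is invariant to adding a constant to every cell", {
  set.seed(6)
  n <- 80
  expr <- matrix(rnorm(n * 15), n, 15,
                 dimnames = list(sprintf("G%05d", 1:n), sprintf("C%02d", 1:15)))
  em1 <- expr_matrix(expr, "continuous")
  em2 <- expr_matrix(expr + 5, "continuous")
  refs <- sprintf("C%02d", 1:10)
  p1 <- infer_cnv_profile(em1, make_ann(n), refs, window = 10)
  p2 <- infer_cnv_profile(em2, make_ann(n), refs, window = 10)
  expect_equal(p1$smoothed, p2$smoothed, tolerance = 1e-12)
})

test_that("short chromosomes are excluded with a warning; empty reference errors", {
  n <- 30
  expr <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(sprintf("G%05d", 1:n), sprintf("C%02d", 1:6)))
  ann <- make_ann(n)
  ann$chrom[26:30] <- "chrTiny"
  em <- expr_matrix(expr, "continuous")
  expect_warning(prof <- infer_cnv_profile(em, genome_annotation(ann[, ]),
                                           "C01", window = 5), "chrTiny")
  expect_equal(ncol(prof$smoothed), 25)
  expect_error(infer_cnv_profile(em, make_ann(n), character()), "empty reference")
})

test_that("robust-Z focal calls match hand arithmetic and the epsilon rule", {
  smoothed <- matrix(0, 12, 2, dimnames = list(sprintf("C%02d", 1:12),
                                               c("CDKN2A", "KRAS")))
  smoothed[1:11, "CDKN2A"] <- 1:11        # reference: median 6, MAD 3 * 1.4826
  smoothed[12, "CDKN2A"] <- 16
  smoothed[1:11, "KRAS"] <- 2             # constant reference -> MAD floored
  smoothed[12, "KRAS"] <- 2.5
  prof <- structure(list(smoothed = smoothed,
                         cnv_score = rowMeans(smoothed^2),
                         reference_cells = sprintf("C%02d", 1:11)),
                    class = "cnv_profile")
  calls <- call_focal_events(prof, c("CDKN2A", "KRAS"))
  expect_equal(unname(calls$z["C12", "CDKN2A"]), (16 - 6) / (3 * 1.4826),
               tolerance = 1e-4)                  # ~2.248
  expect_equal(unname(calls$call["C12", "CDKN2A"]), "gain")
  expect_equal(unname(calls$call["C06", "CDKN2A"]), "neutral")  # at the median
  expect_equal(unname(calls$call["C12", "KRAS"]), "gain")       # epsilon floor
  expect_equal(unname(calls$call["C05", "KRAS"]), "neutral")    # equal to median
})

test_that("missing drivers are non-fatal; call counts are monotone in thresholds", {
  set.seed(7)
  smoothed <- matrix(rnorm(300), 100, 3,
                     dimnames = list(sprintf("C%03d", 1:100),
                                     c("TP53", "KRAS", "CDKN2B")))
  prof <- structure(list(smoothed = smoothed, cnv_score = rowMeans(smoothed^2),
                         reference_cells = sprintf("C%03d", 1:50)),
                    class = "cnv_profile")
  expect_warning(calls <- call_focal_events(prof, c("TP53", "ABSENT")),
                 "ABSENT")
  expect_equal(calls$missing, "ABSENT")
  g1 <- sum(call_focal_events(prof, "TP53", z_gain = 1)$call == "gain")
  g2 <- sum(call_focal_events(prof, "TP53", z_gain = 2)$call == "gain")
  g3 <- sum(call_focal_events(prof, "TP53", z_gain = 3)$call == "gain")
  expect_true(g1 >= g2 && g2 >= g3)
})

test_that("resolution selection recovers three well-separated blobs", {
  set.seed(8)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  emb <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(100, 0, 0.1), 50, 2), 2, centers[k, ], "+")))
  rownames(emb) <- sprintf("C%03d", 1:150)
  sol <- select_resolution(emb, grid = seq(0.2, 2.0, 0.2), seed = 1)
  expect_equal(length(unique(sol$membership)), 3)
  expect_gt(max(sol$silhouette), 0.7)
  expect_true(sol$resolution %in% seq(0.2, 2.0, 0.2))
})

test_that("resolution selection guards and forced choice", {
  set.seed(9)
  emb <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("C%02d", 1:20), NULL))
  sol <- select_resolution(emb, grid = 1.0, seed = 1)
  expect_equal(sol$resolution, 1.0)
  expect_error(select_resolution(matrix(1, 5, 2)), "identical")
  expect_error(select_resolution(emb[1:2, ]), "3 points")
  expect_error(select_resolution(emb, grid = numeric()), "empty")
})

test_that("an injectable partitioner is honored and ties go to the smallest resolution", {
  set.seed(10)
  emb <- rbind(matrix(rnorm(40, 0, .1), 20, 2),
               matrix(rnorm(40, 5, .1), 20, 2))
  rownames(emb) <- sprintf("C%02d", 1:40)
  fixed <- function(graph, resolution, seed) rep(1:2, each = 20)
  sol <- select_resolution(emb, grid = c(0.5, 1.0), partitioner = fixed)
  expect_equal(sol$resolution, 0.5)   # identical partitions -> smallest wins
  expect_equal(unname(sol$membership), rep(1:2, each = 20))
})

test_that("malignancy labeling follows the evidence rules", {
  cells <- sprintf("C%03d", 1:90)
  refs <- cells[1:30]
  smoothed <- matrix(rnorm(90 * 10, 0, 0.05), 90, 10,
                     dimnames = list(cells, sprintf("G%05d", 1:10)))
  smoothed[61:90, ] <- smoothed[61:90, ] + 1    # high-CNV cluster
  prof <- structure(list(smoothed = smoothed, cnv_score = rowMeans(smoothed^2),
                         reference_cells = refs), class = "cnv_profile")
  memb <- setNames(rep(1:2, each = 30), cells[31:90])
  calls <- call_focal_events(prof, "G00005")
  lab <- label_malignant(prof, memb, calls)
  expect_true(all(lab$labels[refs] == "reference"))
  expect_true(all(lab$labels[cells[61:90]] == "tumor-like"))
  expect_true(all(lab$labels[cells[31:60]] == "normal-like"))
  # driver-fraction route: flat CNV score but pervasive driver losses
  smoothed2 <- matrix(rnorm(90 * 10, 0, 0.05), 90, 10,
                      dimnames = dimnames(smoothed))
  smoothed2[61:90, 5] <- -2
  prof2 <- structure(list(smoothed = smoothed2,
                          cnv_score = rep(0, 90) |> setNames(cells),
                          reference_cells = refs), class = "cnv_profile")
  calls2 <- call_focal_events(prof2, "G00005")
  lab2 <- label_malignant(prof2, memb, calls2)
  expect_true(all(lab2$labels[cells[61:90]] == "tumor-like"))
  expect_error(label_malignant(prof, setNames(integer(), character()), calls),
               "clusters")
})
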