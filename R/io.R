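# Readers/writers for the plain-text formats the pipeline exchanges.
# All coordinates are 0-based half-open internally; BED input is taken as
# already 0-based half-open. Gene identifiers are matched case-sensitively.

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a line are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return a `gene_set_collection`: named list with elements
#'   `list(description =, genes =)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      .stopf("GMT parse error at line %d: fewer than 3 tab-separated fields", i)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) .stopf("GMT parse error at line %d: empty gene list", i)
    if (anyDuplicated(genes)) {
      .warnf("GMT line %d ('%s'): duplicate genes removed", i, f[[1]])
      genes <- genes[!duplicated(genes)]
    }
    nms[i] <- f[[1]]
    sets[[i]] <- list(description = f[[2]], genes = genes)
  }
  if (anyDuplicated(nms)) .stopf("duplicate gene-set names in GMT")
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d..%d genes each\n",
              length(x), min(lengths(lapply(x, `[[`, "genes"))),
              max(lengths(lapply(x, `[[`, "genes")))))
  invisible(x)
}

#' Write a GMT gene-set collection
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix (dense TSV or MatrixMarket triplet)
#'
#' TSV layout: header row of sample names, first column gene ids. MTX layout:
#' coordinate file plus companion `<path>.rows.txt` / `<path>.cols.txt` name
#' files (one name per line).
#'
#' @param path matrix file.
#' @param format `"tsv"` or `"mtx"`.
#' @param mode `"continuous"` or `"counts"`; counts mode enforces
#'   non-negative integrality.
#' @return an [expr_matrix()].
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"),
                        mode = c("continuous", "counts")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  } else {
    rows_f <- paste0(path, ".rows.txt")
    cols_f <- paste0(path, ".cols.txt")
    if (!file.exists(rows_f) || !file.exists(cols_f))
      .stopf("MTX companion name files missing: %s / %s", rows_f, cols_f)
    sm <- Matrix::readMM(path)
    m <- as.matrix(sm)
    rownames(m) <- readLines(rows_f, warn = FALSE)
    colnames(m) <- readLines(cols_f, warn = FALSE)
  }
  expr_matrix(m, mode)
}

#' Write an expression matrix
#' @param x an [expr_matrix()] (any named numeric matrix works).
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (writes companion name files).
#' @export
write_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"), "CsparseMatrix"), path)
    writeLines(rownames(x), paste0(path, ".rows.txt"))
    writeLines(colnames(x), paste0(path, ".cols.txt"))
  }
  invisible(path)
}

#' Read a survival table
#'
#' Expects columns `subject_id`, `time`, `event`; extra columns are retained
#' as covariates.
#' @param path TSV file.
#' @return a [survival_table()].
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  survival_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_survival
#' @param surv a `survival_table`.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(as.data.frame(surv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read JASPAR-style position weight matrices
#'
#' Parses blocks of the form
#' ```
#' >MA0001.1 NAME
#' A [ 10  2 ... ]
#' C [  0  5 ... ]
#' G [ ... ]
#' T [ ... ]
#' ```
#' Count matrices get a pseudocount of 0.5 per cell before column
#' normalization; probability matrices (columns already summing to 1) are
#' returned unchanged.
#'
#' @param path motif text file.
#' @param pseudocount added per cell to count matrices (default 0.5).
#' @return list of `pwm` objects: `list(motif_id =, probs = 4 x width)`
#'   with rows A, C, G, T.
#' @export
read_pwm <- function(path, pseudocount = 0.5) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) .stopf("no motif headers ('>') found in %s", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[b]])
    motif_id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(starts[b] + 1L):ends[b]]
    if (length(body) != 4)
      .stopf("motif %s: expected 4 base rows, got %d", motif_id, length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("[][]", " ", l)
      toks <- strsplit(trimws(l), "\\s+")[[1]]
      list(base = toks[1], vals = as.numeric(toks[-1]))
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      .stopf("motif %s: rows must be labeled A, C, G, T", motif_id)
    w <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(w)) != 1)
      .stopf("motif %s: unequal row lengths", motif_id)
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(m) <- bases
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(m < 0) || any(!is.finite(m)))
      .stopf("motif %s: negative or non-finite entries", motif_id)
    cs <- colSums(m)
    if (all(abs(cs - 1) <= 1e-6)) {
      probs <- m
    } else {
      m <- m + pseudocount
      probs <- sweep(m, 2, colSums(m), "/")
    }
    out[[b]] <- structure(list(motif_id = motif_id, probs = probs),
                          class = "pwm")
  }
  out
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: width %d\n", x$motif_id, ncol(x$probs)))
  invisible(x)
}

#' Validate and construct a pwm from a probability matrix
#' @param motif_id identifier.
#' @param probs 4 x width matrix, rows A,C,G,T, columns summing to 1.
#' @export
pwm <- function(motif_id, probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) .stopf("pwm must have 4 rows")
  if (is.null(rownames(probs))) rownames(probs) <- c("A", "C", "G", "T")
  probs <- probs[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(probs < 0)) .stopf("pwm probabilities must be non-negative")
  if (any(abs(colSums(probs) - 1) > 1e-6)) .stopf("pwm columns must sum to 1")
  structure(list(motif_id = motif_id, probs = probs), class = "pwm")
}

#' Write motifs in the JASPAR-style dialect read_pwm() accepts
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @export
write_pwm <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$motif_id),
      vapply(c("A", "C", "G", "T"), function(b)
        sprintf("%s [ %s ]", b, paste(format(p$probs[b, ], digits = 17),
                                      collapse = " ")), character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED-like gene annotation
#'
#' Six columns: chrom, start, end, gene_id, score (ignored), strand.
#' Coordinates are 0-based half-open.
#'
#' @param path BED-like file (no header).
#' @return data.frame with columns gene_id, chrom, start, end, strand.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) .stopf("annotation needs 6 BED columns")
  ann <- data.frame(gene_id = as.character(df[[4]]), chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    strand = as.character(df[[6]]), stringsAsFactors = FALSE)
  genome_annotation(ann)
}

#' @rdname read_annotation
#' @param ann annotation data.frame (gene_id, chrom, start, end, strand).
#' @export
genome_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id)) .stopf("duplicate gene ids in annotation")
  if (!all(ann$strand %in% c("+", "-"))) .stopf("strand must be '+' or '-'")
  if (any(ann$start >= ann$end)) .stopf("annotation requires start < end")
  class(ann) <- unique(c("genome_annotation", class(ann)))
  ann
}

#' @rdname read_annotation
#' @export
write_annotation <- function(ann, path) {
  bed <- data.frame(ann$chrom, ann$start, ann$end, ann$gene_id, 0L, ann$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- names(seqs)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
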