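#' @keywords internal
"_PACKAGE"

# rank with deterministic tie-breaking: sort by value descending, ties broken
# by lexicographic gene id so results are bit-reproducible across platforms
.rank_desc <- function(x) {
  ids <- names(x)
  ord <- order(-x, ids, method = "radix")
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  names(r) <- ids
  r
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 0

# seeded evaluation that restores the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Construct a validated expression matrix
#'
#' The common currency of the pipeline: a numeric matrix with genes in rows
#' and samples (or cells) in columns, plus a declared measurement mode.
#'
#' @param values numeric matrix with unique row and column names.
#' @param mode `"continuous"` (log-normalized or otherwise real-valued) or
#'   `"counts"` (non-negative integers, as from UMI counting).
#' @return the matrix with a `mode` attribute, validated.
#' @export
expr_matrix <- function(values, mode = c("continuous", "counts")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    .stopf("duplicate gene names: %s",
           paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    .stopf("duplicate sample names")
  if (any(!is.finite(values)))
    .stopf("expression matrix contains non-finite values")
  if (mode == "counts") {
    if (any(values < 0) || any(values != round(values)))
      .stopf("counts mode requires non-negative integer values")
  }
  attr(values, "mode") <- mode
  values
}

#' Measurement mode of an expression matrix
#' @param x an [expr_matrix()].
#' @return `"continuous"` or `"counts"`.
#' @export
expr_mode <- function(x) attr(x, "mode") %||% "continuous"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a validated survival table
#'
#' @param df data.frame containing columns `subject_id`, `time` (days,
#'   strictly positive) and `event` (0 = censored, 1 = event). Any further
#'   columns are retained as covariates.
#' @return the validated data.frame with class `survival_table`.
#' @export
survival_table <- function(df) {
  need <- c("subject_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("survival table missing column(s): %s", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) .stopf("duplicate subject ids")
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time <= 0))
    .stopf("follow-up time must be finite and strictly positive")
  if (!all(df$event %in% c(0, 1))) .stopf("event indicator must be 0 or 1")
  df$event <- as.integer(df$event)
  class(df) <- unique(c("survival_table", class(df)))
  df
}

# align a feature matrix (features x subjects) with a survival table
.align_features <- function(features, surv) {
  ids <- intersect(colnames(features), surv$subject_id)
  if (!length(ids)) .stopf("no subjects shared between features and survival table")
  list(features = features[, ids, drop = FALSE],
       surv = surv[match(ids, surv$subject_id), , drop = FALSE])
}
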