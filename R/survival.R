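# Pathway-level prognostic framework: cohort splitting, univariate Cox
# screening with FDR control, bootstrap elastic-net stability selection,
# learner benchmarking, discrimination metrics and Shapley attribution.

#' Landmark-stratified train/validation split
#'
#' Guarantees that subjects followed to approximately each landmark (within
#' `tolerance` days) are represented in both partitions, then assigns the
#' remaining subjects by an event-stratified random draw at the requested
#' ratio.
#'
#' @param surv a [survival_table()], >= 10 subjects.
#' @param ratio training fraction (default 0.7).
#' @param landmarks follow-up landmarks in days (default 1, 3 and 5 years).
#' @param tolerance half-width in days of the landmark window (default 90).
#' @param seed RNG seed.
#' @return object of class `cohort_split` with `train_ids`,
#'   `validation_ids`, and the parameters used.
#' @export
landmark_stratified_split <- function(surv, ratio = 0.7,
                                      landmarks = c(365, 1095, 1825),
                                      tolerance = 90, seed = 1) {
  n <- nrow(surv)
  if (n < 10) .stopf("need at least 10 subjects, got %d", n)
  .with_seed(seed, {
    ids <- surv$subject_id
    train <- character(); val <- character()
    pool <- ids
    for (L in landmarks) {
      elig <- intersect(pool, ids[abs(surv$time - L) <= tolerance])
      if (length(elig) >= 2) {
        pick <- sample(elig, 2)
        train <- c(train, pick[1]); val <- c(val, pick[2])
        pool <- setdiff(pool, pick)
      }
    }
    target_train <- round(ratio * n)
    need <- max(0L, min(target_train - length(train), length(pool)))
    ev <- surv$event[match(pool, ids)]
    add <- character()
    for (g in unique(ev)) {
      sub <- pool[ev == g]
      k <- round(need * length(sub) / length(pool))
      add <- c(add, sample(sub, min(k, length(sub))))
    }
    # round-off correction toward the exact target
    short <- need - length(add)
    rest <- setdiff(pool, add)
    if (short > 0) add <- c(add, sample(rest, short))
    if (short < 0) add <- add[seq_len(need)]
    train <- c(train, add)
    val <- c(val, setdiff(pool, add))
    structure(list(train_ids = sort(train), validation_ids = sort(val),
                   ratio = ratio, landmarks = landmarks,
                   tolerance = tolerance, seed = seed),
              class = "cohort_split")
  })
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("cohort_split: %d train / %d validation (ratio %.2f)\n",
              length(x$train_ids), length(x$validation_ids), x$ratio))
  invisible(x)
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Maximizes the Breslow partial likelihood via Newton iterations (up to 100)
#' and reports Wald statistics from the normal approximation. Monotone
#' likelihood (separation) is flagged when any coefficient exceeds 20 in
#' magnitude.
#'
#' @param covariates numeric matrix, subjects x covariates (column names
#'   used); rows aligned to `surv`.
#' @param surv a [survival_table()].
#' @return object of class `cox_fit` with per-covariate `coef`, `se`, `z`,
#'   `p`, `hr`, `hr_lower`, `hr_upper`, plus `loglik` and `ties`.
#' @export
fit_cox <- function(covariates, surv) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (nrow(covariates) != nrow(surv))
    .stopf("covariates (%d rows) not aligned to survival table (%d subjects)",
           nrow(covariates), nrow(surv))
  sds <- apply(covariates, 2, stats::sd)
  if (any(sds == 0))
    .stopf("constant covariate: %s", paste(colnames(covariates)[sds == 0], collapse = ", "))
  if (nrow(covariates) <= ncol(covariates))
    .stopf("need more subjects than covariates")
  fit <- survival::coxph(
    survival::Surv(surv$time, surv$event) ~ covariates,
    ties = "breslow",
    control = survival::coxph.control(iter.max = 100, eps = 1e-10))
  if (fit$iter >= 100)
    .stopf("Cox fit did not converge within %d iterations", fit$iter)
  beta <- unname(fit$coefficients)
  if (any(abs(beta) > 20))
    .stopf("monotone likelihood (separation): |beta| > 20")
  se <- sqrt(diag(as.matrix(fit$var)))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(
    coef = stats::setNames(beta, colnames(covariates)),
    se = stats::setNames(se, colnames(covariates)),
    z = z, p = stats::setNames(p, colnames(covariates)),
    hr = exp(beta),
    hr_lower = exp(beta - 1.96 * se), hr_upper = exp(beta + 1.96 * se),
    loglik = fit$loglik[2], ties = "breslow", n = nrow(covariates)),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  df <- data.frame(coef = x$coef, HR = x$hr, lower = x$hr_lower,
                   upper = x$hr_upper, p = x$p)
  cat(sprintf("cox_fit (Breslow ties, n = %d)\n", x$n))
  print(df, digits = 3)
  invisible(x)
}

#' Univariate Cox screen with Benjamini-Hochberg FDR control
#'
#' One single-covariate Cox fit per feature; features with zero variance are
#' reported as skipped, not failed.
#'
#' @param features features x subjects matrix, or a `pathway_scores` object
#'   (its NES matrix is used).
#' @param surv a [survival_table()] covering the feature columns.
#' @param fdr retention threshold on BH-adjusted q (default 0.05).
#' @return object of class `screen_result`: data.frame `table` (feature,
#'   coef, p, q), `retained` feature names, `skipped` zero-variance names.
#' @export
univariate_cox_screen <- function(features, surv, fdr = 0.05) {
  if (inherits(features, "pathway_scores")) features <- features$nes
  al <- .align_features(features, surv)
  features <- al$features; surv <- al$surv
  if (!ncol(features)) .stopf("zero aligned subjects")
  sds <- apply(features, 1, stats::sd)
  skipped <- rownames(features)[sds == 0]
  use <- rownames(features)[sds > 0]
  res <- lapply(use, function(f) {
    fit <- fit_cox(matrix(features[f, ], ncol = 1,
                          dimnames = list(NULL, f)), surv)
    c(coef = unname(fit$coef), p = unname(fit$p))
  })
  tab <- data.frame(feature = use,
                    coef = vapply(res, `[[`, numeric(1), "coef"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$q, tab$p, tab$feature), ]
  rownames(tab) <- NULL
  structure(list(table = tab, retained = tab$feature[tab$q <= fdr],
                 skipped = skipped, fdr = fdr),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d/%d features retained at FDR %.2f (%d skipped)\n",
              length(x$retained), nrow(x$table), x$fdr, length(x$skipped)))
  invisible(x)
}

#' Bootstrap stability selection with an elastic-net Cox model
#'
#' Fits a penalized Cox model on bootstrap resamples (70% of subjects, drawn
#' with replacement) over a 50-point log-spaced lambda path from the
#' data-derived maximum down to 1% of it; a feature counts as selected in a
#' resample when its coefficient is non-zero at any lambda. The selection
#' frequency across resamples measures feature stability.
#'
#' Note that the any-lambda selection rule is permissive: near the low end
#' of the path the model is only lightly penalized, so features with modest
#' marginal association also enter and selection frequencies concentrate
#' near 1 when subjects outnumber features. Frequencies are best read
#' comparatively (planted/strong features reach exactly 1) or recomputed
#' over a shorter path via `lambda_min_ratio`.
#'
#' @param features features x subjects matrix (or `pathway_scores`).
#' @param surv a [survival_table()].
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param subsample resample size as a fraction of subjects (default 0.7).
#' @param l1_ratio elastic-net mixing parameter (default 0.1).
#' @param n_lambdas points on the lambda path (default 50).
#' @param seed RNG seed.
#' @return object of class `stability_result` with per-feature `frequency`,
#'   and the resampling parameters.
#' @export
#' @param lambda_min_ratio lower end of the lambda path as a fraction of
#'   the data-derived maximum (default 0.01).
stability_selection <- function(features, surv, n_resamples = 1000,
                                subsample = 0.7, l1_ratio = 0.1,
                                n_lambdas = 50, lambda_min_ratio = 0.01,
                                seed = 1) {
  if (inherits(features, "pathway_scores")) features <- features$nes
  if (n_resamples < 1) .stopf("n_resamples must be >= 1")
  if (nrow(features) < 2) .stopf("need at least 2 features")
  al <- .align_features(features, surv)
  x <- t(al$features); surv <- al$surv
  n <- nrow(x)
  m <- max(2L, round(subsample * n))
  counts <- stats::setNames(integer(ncol(x)), colnames(x))
  .with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      repeat {   # a usable resample needs >= 2 events and varying features
        idx <- sample.int(n, m, replace = TRUE)
        if (sum(surv$event[idx]) >= 2 &&
            all(apply(x[idx, , drop = FALSE], 2, stats::sd) > 0)) break
      }
      fit <- glmnet::glmnet(
        x[idx, , drop = FALSE],
        survival::Surv(surv$time[idx], surv$event[idx]),
        family = "cox", alpha = l1_ratio,
        nlambda = n_lambdas, lambda.min.ratio = lambda_min_ratio,
        standardize = TRUE)
      nz <- rowSums(abs(as.matrix(fit$beta)) > 0) > 0
      counts[names(nz)[nz]] <- counts[names(nz)[nz]] + 1L
    }
  })
  structure(list(frequency = counts / n_resamples, n_resamples = n_resamples,
                 subsample = subsample, l1_ratio = l1_ratio,
                 n_lambdas = n_lambdas, lambda_min_ratio = lambda_min_ratio,
                 seed = seed),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability_result: %d features, %d resamples; top frequencies:\n",
              length(x$frequency), x$n_resamples))
  print(utils::head(sort(x$frequency, decreasing = TRUE), 5))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Event-anchored comparable pairs: subject i anchors a pair with j when
#' `time_i < time_j` and i had the event. Risk ties count 0.5. Returns 0.5
#' with a warning when no pair is comparable.
#'
#' @param risk numeric risk score (higher = worse), aligned to `surv`.
#' @param surv a [survival_table()].
#' @return concordance in \[0,1\].
#' @export
concordance_index <- function(risk, surv) {
  if (length(risk) != nrow(surv)) .stopf("risk length != number of subjects")
  t <- surv$time; d <- surv$event
  num <- 0; den <- 0
  for (i in which(d == 1)) {
    later <- t > t[i]
    if (!any(later)) next
    den <- den + sum(later)
    num <- num + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (den == 0) {
    .warnf("no comparable pairs; returning 0.5")
    return(0.5)
  }
  num / den
}

# Kaplan-Meier estimate of the censoring survival function G, evaluated
# left-continuously at arbitrary times
.censor_km <- function(surv) {
  fit <- survival::survfit(survival::Surv(surv$time, 1 - surv$event) ~ 1)
  steps <- stats::stepfun(fit$time, c(1, fit$surv), right = TRUE)
  function(u) pmax(steps(u), 1e-12)  # right=TRUE gives the left limit G(u-)
}

#' Time-dependent AUC (IPCW cumulative/dynamic)
#'
#' Cumulative cases (event by the horizon) vs dynamic controls (still at
#' risk), with inverse-probability-of-censoring weights from the
#' Kaplan-Meier censoring estimator. Horizons beyond the maximum follow-up
#' are reported as `NA`.
#'
#' @param risk numeric risk score, aligned to `surv`.
#' @param surv a [survival_table()].
#' @param horizons evaluation times in days (default 12, 36 and 60 months at
#'   30.4375 days/month).
#' @return named numeric vector of AUC values, one per horizon.
#' @export
time_dependent_auc <- function(risk, surv,
                               horizons = round(c(12, 36, 60) * 30.4375)) {
  if (length(risk) != nrow(surv)) .stopf("risk length != number of subjects")
  G <- .censor_km(surv)
  out <- stats::setNames(rep(NA_real_, length(horizons)),
                         paste0("t", horizons))
  for (h in seq_along(horizons)) {
    t0 <- horizons[h]
    if (t0 >= max(surv$time)) next  # undefined beyond follow-up
    case <- surv$time <= t0 & surv$event == 1
    ctrl <- surv$time > t0
    if (!any(case) || !any(ctrl)) next
    w <- 1 / G(surv$time[case])     # left-limit weights per case
    num <- 0
    for (i in seq_along(w)) {
      r <- risk[case][i]
      num <- num + w[i] * (sum(r > risk[ctrl]) + 0.5 * sum(r == risk[ctrl]))
    }
    out[h] <- num / (sum(w) * sum(ctrl))
  }
  out
}

#' Two-group Kaplan-Meier curves and log-rank test
#'
#' @param surv a [survival_table()].
#' @param group logical or two-level vector aligned to `surv`.
#' @return object of class `km_logrank`: per-group product-limit curves
#'   (`curves`: group, time, n_risk, n_event, surv), `chisq`, `p`.
#' @export
km_logrank <- function(surv, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) .stopf("exactly two non-empty groups required")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ group)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(surv$time, surv$event) ~ group)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strata), time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv, stringsAsFactors = FALSE)
  structure(list(curves = curves, chisq = chisq, p = p,
                 observed = sd$obs, expected = sd$exp),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.4g, p = %.4g\n", x$chisq, x$p))
  invisible(x)
}

#' Optimal survival cutpoint for a continuous marker
#'
#' Scans every midpoint between consecutive sorted unique marker values that
#' leaves at least `min_group_fraction` of subjects in each arm and returns
#' the cutpoint maximizing the log-rank statistic. The returned p-value is
#' selection-biased (maximally selected statistic) and is flagged as such.
#'
#' @param marker numeric vector aligned to `surv`; >= 2 distinct values.
#' @param surv a [survival_table()].
#' @param min_group_fraction minimum fraction per arm (default 0.1).
#' @return object of class `cutpoint_result`: `cutpoint`, `labels`
#'   ("high"/"low"), `chisq`, `p`, `selection_biased = TRUE`.
#' @export
optimal_cutpoint <- function(marker, surv, min_group_fraction = 0.1) {
  u <- sort(unique(marker))
  if (length(u) < 2) .stopf("marker must have at least 2 distinct values")
  mids <- (u[-1] + u[-length(u)]) / 2
  n <- length(marker)
  ok <- vapply(mids, function(cc) {
    hi <- sum(marker > cc)
    min(hi, n - hi) >= min_group_fraction * n
  }, logical(1))
  mids <- mids[ok]
  if (!length(mids)) .stopf("no admissible cutpoint at min_group_fraction %.2f",
                            min_group_fraction)
  stat <- vapply(mids, function(cc)
    km_logrank(surv, marker > cc)$chisq, numeric(1))
  best <- which.max(stat)
  res <- km_logrank(surv, marker > mids[best])
  structure(list(cutpoint = mids[best],
                 labels = ifelse(marker > mids[best], "high", "low"),
                 chisq = res$chisq, p = res$p, selection_biased = TRUE),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("cutpoint %.4g: log-rank chi-square %.3g, p = %.3g (selection-biased)\n",
              x$cutpoint, x$chisq, x$p))
  invisible(x)
}

#' Elastic-net Cox learner for the benchmarking harness
#'
#' The shipped reference learner. A learner specification is a list with
#' `name`, `grid` (named list of candidate hyperparameter values sampled
#' uniformly during random search), `fit(features, surv, params)` returning
#' a model object, and `risk(model, features)` returning one real risk score
#' per subject (higher = worse). `features` is subjects x features.
#'
#' @param alpha_grid candidate elastic-net mixing values.
#' @param lambda_grid candidate penalty values.
#' @export
learner_coxnet <- function(alpha_grid = c(0.01, 0.1, 0.5, 0.9),
                           lambda_grid = 10^seq(-3, 0, length.out = 10)) {
  list(
    name = "coxnet",
    grid = list(alpha = alpha_grid, lambda = lambda_grid),
    fit = function(features, surv, params) {
      glmnet::glmnet(features, survival::Surv(surv$time, surv$event),
                     family = "cox", alpha = params$alpha,
                     lambda = c(params$lambda * 2, params$lambda))
    },
    risk = function(model, features) {
      drop(stats::predict(model, features, type = "link")[, 2])
    })
}

.check_learner <- function(sp) {
  ok <- is.list(sp) && all(c("name", "grid", "fit", "risk") %in% names(sp)) &&
    is.function(sp$fit) && is.function(sp$risk) && is.list(sp$grid)
  if (!ok) .stopf("learner '%s' violates the harness contract",
                  if (is.list(sp) && !is.null(sp$name)) sp$name else "<unnamed>")
}

#' Benchmark survival learners by seeded random search and 5-fold CV
#'
#' For each learner, `n_search` hyperparameter draws are sampled uniformly
#' from its grid; the objective is the mean 5-fold cross-validated C-index
#' on the training cohort. The winning configuration is refit on the full
#' training data and evaluated (C-index and time-dependent AUC) on every
#' supplied cohort.
#'
#' @param features features x subjects training matrix (or
#'   `pathway_scores`).
#' @param surv training [survival_table()].
#' @param learners list of learner specifications (see [learner_coxnet()]).
#' @param n_folds CV folds (default 5).
#' @param n_search random-search draws per learner (default 20).
#' @param cohorts optional named list of `list(features =, surv =)`
#'   evaluation cohorts (the training cohort is always included as
#'   `"train"`).
#' @param horizons td-AUC horizons in days.
#' @param seed RNG seed.
#' @return object of class `benchmark_report`: per-learner best params, CV
#'   C-index, and per-cohort C-index / td-AUC.
#' @export
benchmark_models <- function(features, surv, learners = list(learner_coxnet()),
                             n_folds = 5, n_search = 20, cohorts = NULL,
                             horizons = round(c(12, 36, 60) * 30.4375),
                             seed = 1) {
  if (inherits(features, "pathway_scores")) features <- features$nes
  al <- .align_features(features, surv)
  x <- t(al$features); surv <- al$surv
  n <- nrow(x)
  if (n_folds > n) .stopf("n_folds (%d) exceeds the number of subjects (%d)",
                          n_folds, n)
  for (sp in learners) .check_learner(sp)
  .with_seed(seed, {
    fold <- sample(rep(seq_len(n_folds), length.out = n))
    reports <- lapply(learners, function(sp) {
      draws <- lapply(seq_len(n_search), function(i)
        lapply(sp$grid, function(g) if (length(g) == 1) g[[1]] else sample(g, 1)))
      draws <- unique(draws)
      cv <- vapply(draws, function(params) {
        cs <- vapply(seq_len(n_folds), function(k) {
          tr <- fold != k
          model <- sp$fit(x[tr, , drop = FALSE], surv[tr, , drop = FALSE], params)
          r <- sp$risk(model, x[!tr, , drop = FALSE])
          suppressWarnings(concordance_index(r, surv[!tr, , drop = FALSE]))
        }, numeric(1))
        mean(cs)
      }, numeric(1))
      best <- which.max(cv)
      model <- sp$fit(x, surv, draws[[best]])
      evals <- list(train = list(features = t(x), surv = surv))
      if (!is.null(cohorts)) evals <- c(evals, cohorts)
      perf <- lapply(evals, function(co) {
        xf <- t(co$features)[, , drop = FALSE]
        r <- sp$risk(model, xf)
        list(cindex = suppressWarnings(concordance_index(r, co$surv)),
             td_auc = time_dependent_auc(r, co$surv, horizons))
      })
      list(name = sp$name, best_params = draws[[best]],
           cv_cindex = cv[best], performance = perf, model = model,
           risk_fun = function(features_subj_by_feat)
             sp$risk(model, features_subj_by_feat))
    })
    names(reports) <- vapply(learners, `[[`, character(1), "name")
    structure(list(learners = reports, n_folds = n_folds,
                   n_search = n_search, seed = seed),
              class = "benchmark_report")
  })
}

#' @export
print.benchmark_report <- function(x, ...) {
  for (r in x$learners)
    cat(sprintf("%s: CV C-index %.3f (train C-index %.3f)\n",
                r$name, r$cv_cindex, r$performance$train$cindex))
  invisible(x)
}

#' Monte-Carlo Shapley attribution for a fitted risk model
#'
#' For each patient and each sampled feature ordering, features are switched
#' one by one from the baseline (training mean) to the patient's value and
#' the marginal change in predicted risk is credited to the switched
#' feature; attributions average over orderings. Global importance is the
#' per-feature mean over patients; a positive mean marks a risk-increasing
#' feature.
#'
#' @param model function taking a subjects x features matrix and returning a
#'   numeric risk per row.
#' @param features subjects x features matrix to explain.
#' @param n_permutations sampled orderings per patient (>= 1).
#' @param baseline baseline feature vector (default column means).
#' @param seed RNG seed.
#' @return object of class `attribution_matrix`: `phi` (subjects x
#'   features), `importance` (per-feature mean), `baseline`.
#' @export
shapley_importance <- function(model, features, n_permutations = 100,
                               baseline = colMeans(features), seed = 1) {
  stopifnot(n_permutations >= 1)
  features <- as.matrix(features)
  p <- ncol(features)
  base_pred <- model(matrix(baseline, 1, p,
                            dimnames = list(NULL, colnames(features))))
  if (!is.finite(base_pred)) .stopf("non-finite model output at the baseline")
  phi <- matrix(0, nrow(features), p, dimnames = dimnames(features))
  .with_seed(seed, {
    for (s in seq_len(nrow(features))) {
      xs <- features[s, ]
      acc <- numeric(p)
      for (b in seq_len(n_permutations)) {
        ord <- sample.int(p)
        cur <- baseline
        prev <- base_pred
        # evaluate the whole switching path in one batched model call
        path <- matrix(baseline, p, p, byrow = TRUE,
                       dimnames = list(NULL, colnames(features)))
        for (j in seq_len(p)) {
          cur[ord[j]] <- xs[ord[j]]
          path[j, ] <- cur
        }
        preds <- model(path)
        if (any(!is.finite(preds))) .stopf("non-finite model output")
        acc[ord] <- acc[ord] + diff(c(prev, preds))
      }
      phi[s, ] <- acc / n_permutations
    }
  })
  structure(list(phi = phi, importance = colMeans(phi), baseline = baseline,
                 n_permutations = n_permutations),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("attribution_matrix: %d patients x %d features; top importance:\n",
              nrow(x$phi), ncol(x$phi)))
  print(utils::head(sort(x$importance, decreasing = TRUE), 5))
  invisible(x)
}
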