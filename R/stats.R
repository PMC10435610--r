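# Cohort-level statistics: impairment classification, change scores,
# paired tests, covariate screening, backward-elimination regression,
# Bonferroni correction.

#' Classify cognitive impairment from a Z-score
#'
#' A demographically adjusted test Z-score flags impairment when strictly
#' below -1.5; the boundary value -1.5 itself is not impaired. Missing
#' scores propagate as `NA`, never as `FALSE`.
#'
#' @param z Numeric vector of Z-scores.
#' @param cutoff Impairment cut-off (default -1.5).
#' @return Logical vector (`NA` where `z` is missing).
#' @export
classify_impairment <- function(z, cutoff = -1.5) {
  if (!is.numeric(z)) stop("z must be numeric")
  if (any(is.infinite(z), na.rm = TRUE)) stop("z must be finite")
  z < cutoff
}

#' Per-subject change scores (T2 - T1)
#'
#' One record per subject present at both timepoints. Deltas are T2 minus
#' T1; a subject missing one component of a given measure is omitted for
#' that measure only (the delta is `NA`), and omission counts are attached
#' as an attribute.
#'
#' @param cohort Data frame with columns `subject_id`, `timepoint`
#'   (values `"T1"`/`"T2"`), and the measure columns.
#' @param measures Character vector of measure column names; defaults to
#'   `ec_fpn` plus every column starting with `ef_`.
#' @return Data frame of `subject_id` and `delta_<measure>` columns, with
#'   attribute `n_omitted` (named integer vector of per-measure NA
#'   counts).
#' @export
change_scores <- function(cohort, measures = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "timepoint") %in% names(cohort)))
  if (!all(cohort$timepoint %in% c("T1", "T2"))) {
    stop("timepoint must be 'T1' or 'T2'")
  }
  if (anyDuplicated(cohort[c("subject_id", "timepoint")])) {
    stop("at most one row per subject x timepoint")
  }
  if (is.null(measures)) {
    measures <- intersect(c("ec_fpn", grep("^ef_", names(cohort), value = TRUE)),
                          names(cohort))
  }
  t1 <- cohort[cohort$timepoint == "T1", , drop = FALSE]
  t2 <- cohort[cohort$timepoint == "T2", , drop = FALSE]
  ids <- intersect(t1$subject_id, t2$subject_id)
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  omitted <- integer(0)
  for (m in measures) {
    d <- t2[[m]][match(ids, t2$subject_id)] - t1[[m]][match(ids, t1$subject_id)]
    out[[paste0("delta_", m)]] <- d
    omitted[m] <- sum(is.na(d))
  }
  attr(out, "n_omitted") <- omitted
  out
}

#' Paired change test with a normality gate
#'
#' Tests whether paired values changed between timepoints: differences are
#' screened with Shapiro-Wilk at `alpha_normality`; a paired t-test is
#' used when the differences look normal, a two-sided Wilcoxon signed-rank
#' test otherwise (exact p for n <= 25, normal approximation with
#' continuity correction above). All-zero differences return statistic 0
#' and p = 1.
#'
#' @param values_t1,values_t2 Paired numeric vectors; pairs with a missing
#'   component are dropped.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return List: `test_used` (`"paired-t"` or `"wilcoxon"`), `statistic`,
#'   `p_value`, `n_pairs`.
#' @export
paired_change_test <- function(values_t1, values_t2, alpha_normality = 0.05) {
  if (length(values_t1) != length(values_t2)) {
    stop("paired vectors differ in length")
  }
  ok <- stats::complete.cases(values_t1, values_t2)
  d <- values_t2[ok] - values_t1[ok]
  n <- length(d)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n)
  if (all(d == 0)) {
    return(list(test_used = "paired-t", statistic = 0, p_value = 1, n_pairs = n))
  }
  normal <- if (stats::sd(d) == 0) FALSE else {
    stats::shapiro.test(d)$p.value >= alpha_normality
  }
  if (normal) {
    tt <- stats::t.test(d)
    list(test_used = "paired-t", statistic = unname(tt$statistic),
         p_value = tt$p.value, n_pairs = n)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = n <= 25, correct = TRUE)
    )
    list(test_used = "wilcoxon", statistic = unname(wt$statistic),
         p_value = wt$p.value, n_pairs = n)
  }
}

#' Screen candidate covariates against a dependent variable
#'
#' Selects covariates with a significant (p < `alpha`) univariate
#' association with the dependent variable: continuous candidates by
#' correlation (Pearson when both variables pass a Shapiro-Wilk gate,
#' Spearman otherwise), binary candidates by a two-group comparison
#' (t-test when both groups look normal, Mann-Whitney U otherwise),
#' categorical candidates with more than two levels by one-way ANOVA
#' (Kruskal-Wallis under non-normality). Candidates with a single observed
#' level are skipped with a warning.
#'
#' @param data Data frame holding the dependent and candidate columns.
#' @param dependent Name of the dependent column (numeric).
#' @param candidates Character vector of candidate column names.
#' @param kinds Named character vector mapping each candidate to
#'   `"continuous"`, `"binary"` or `"categorical"`.
#' @param alpha Selection level (default 0.05).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return Data frame with columns `candidate`, `kind`, `test`,
#'   `p_value`, `selected`.
#' @export
screen_covariates <- function(data, dependent, candidates, kinds,
                              alpha = 0.05, alpha_normality = 0.05) {
  stopifnot(is.data.frame(data), dependent %in% names(data))
  if (length(candidates) == 0L) {
    return(data.frame(candidate = character(), kind = character(),
                      test = character(), p_value = numeric(),
                      selected = logical(), stringsAsFactors = FALSE))
  }
  missing_kind <- setdiff(candidates, names(kinds))
  if (length(missing_kind)) {
    stop("no declared kind for candidate(s): ", paste(missing_kind, collapse = ", "))
  }
  y_all <- data[[dependent]]
  looks_normal <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha_normality
  }
  rows <- lapply(candidates, function(cand) {
    x <- data[[cand]]
    ok <- !is.na(x) & !is.na(y_all)
    x <- x[ok]; y <- y_all[ok]
    kind <- kinds[[cand]]
    if (kind == "continuous") {
      method <- if (looks_normal(x) && looks_normal(y)) "pearson" else "spearman"
      p <- suppressWarnings(stats::cor.test(x, y, method = method)$p.value)
      return(data.frame(candidate = cand, kind = kind,
                        test = paste0(method, "-correlation"), p_value = p,
                        stringsAsFactors = FALSE))
    }
    f <- factor(x)
    if (nlevels(f) < 2L) {
      warning("candidate '", cand, "' has a single observed level; skipped")
      return(data.frame(candidate = cand, kind = kind, test = "skipped",
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    if (kind == "binary") {
      if (nlevels(f) != 2L) stop("binary candidate '", cand, "' has ",
                                 nlevels(f), " levels")
      groups <- split(y, f)
      if (all(vapply(groups, looks_normal, logical(1)))) {
        p <- stats::t.test(y ~ f)$p.value
        test <- "t-test"
      } else {
        p <- suppressWarnings(stats::wilcox.test(y ~ f)$p.value)
        test <- "mann-whitney"
      }
    } else if (kind == "categorical") {
      groups <- split(y, f)
      if (all(vapply(groups, looks_normal, logical(1)))) {
        p <- summary(stats::aov(y ~ f))[[1]][["Pr(>F)"]][1]
        test <- "anova"
      } else {
        p <- stats::kruskal.test(y ~ f)$p.value
        test <- "kruskal-wallis"
      }
    } else {
      stop("unknown kind '", kind, "' for candidate '", cand, "'")
    }
    data.frame(candidate = cand, kind = kind, test = test, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Drop near-collinear covariate pairs
#'
#' Among numeric candidate columns, when a pair correlates with
#' `|r| > threshold` the one listed later is dropped (with a message), so
#' the retained set mirrors the declared priority order.
#'
#' @param data Data frame.
#' @param candidates Candidate column names, in priority order.
#' @param threshold Absolute-correlation cut-off (default 0.8).
#' @return Character vector of retained candidate names.
#' @export
drop_collinear <- function(data, candidates, threshold = 0.8) {
  numeric_cands <- candidates[vapply(candidates, function(cc)
    is.numeric(data[[cc]]), logical(1))]
  keep <- candidates
  if (length(numeric_cands) >= 2L) {
    for (i in seq_along(numeric_cands)[-1]) {
      ci <- numeric_cands[i]
      if (!(ci %in% keep)) next
      for (j in seq_len(i - 1L)) {
        cj <- numeric_cands[j]
        if (!(cj %in% keep)) next
        r <- suppressWarnings(stats::cor(data[[ci]], data[[cj]],
                                         use = "complete.obs"))
        if (is.finite(r) && abs(r) > threshold) {
          message("dropping '", ci, "' (|r| = ", round(abs(r), 3),
                  " with '", cj, "')")
          keep <- setdiff(keep, ci)
          break
        }
      }
    }
  }
  keep
}

#' Backward-elimination linear regression
#'
#' Fits ordinary least squares with all entered predictors, then
#' iteratively removes the predictor with the largest p-value while that
#' p-value is at or above `threshold` (default 0.10). Categorical
#' predictors enter as reference-coded indicator columns and are removed
#' indicator by indicator. Analysis is complete-case; the achieved n is
#' reported.
#'
#' @param y Numeric response vector.
#' @param predictors Data frame of predictor columns (numeric, logical, or
#'   factor/character for categoricals).
#' @param threshold Removal criterion: a predictor is removed while its
#'   p-value is `>= threshold` (default 0.10).
#' @param reference_levels Named list mapping a categorical predictor to
#'   its reference level.
#' @return A `regression_result` list: `retained` (data frame with
#'   `predictor`, `beta`, `standardized_beta`, `p_value`), `excluded`
#'   (data frame with `predictor`, `p_value_at_exclusion`), `adj_r2`,
#'   `f_stat`, `df` (numerator, denominator), `model_p`, `n`.
#' @export
backward_regression <- function(y, predictors, threshold = 0.10,
                                reference_levels = list()) {
  stopifnot(is.numeric(y), is.data.frame(predictors))
  if (nrow(predictors) != length(y)) stop("y and predictors disagree in length")
  # expand categoricals to reference-coded indicator columns
  cols <- list()
  for (nm in names(predictors)) {
    v <- predictors[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else if (is.logical(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      f <- factor(v)
      ref <- reference_levels[[nm]]
      if (!is.null(ref)) {
        if (!ref %in% levels(f)) stop("reference level '", ref,
                                      "' not a level of '", nm, "'")
        f <- stats::relevel(f, ref = ref)
      }
      for (lev in levels(f)[-1]) {
        cols[[paste0(nm, ":", lev)]] <- as.numeric(f == lev)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 1L) {
    stop("too few complete cases (n = ", n, ") for ", ncol(X), " predictors")
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    indep <- setdiff(qrX$pivot[seq_len(qrX$rank)], 1L) - 1L
    dep <- setdiff(colnames(X), colnames(X)[indep])
    stop("exact collinearity among predictors: ", paste(dep, collapse = ", "))
  }
  active <- colnames(X)
  excluded <- data.frame(predictor = character(), p_value_at_exclusion = numeric(),
                         stringsAsFactors = FALSE)
  fit_active <- function(active) {
    dat <- data.frame(.y = y, X[, active, drop = FALSE], check.names = FALSE)
    stats::lm(.y ~ ., data = dat)
  }
  repeat {
    if (length(active) == 0L) {
      fit <- stats::lm(y ~ 1)
      break
    }
    fit <- fit_active(active)
    coefs <- summary(fit)$coefficients
    pv <- coefs[-1, 4]
    names(pv) <- active
    worst <- which.max(pv)
    if (pv[worst] >= threshold) {
      excluded <- rbind(excluded, data.frame(
        predictor = active[worst], p_value_at_exclusion = unname(pv[worst]),
        stringsAsFactors = FALSE))
      active <- active[-worst]
    } else break
  }
  sm <- summary(fit)
  if (length(active) > 0L) {
    coefs <- sm$coefficients
    b <- coefs[-1, 1]
    pv <- coefs[-1, 4]
    sdx <- apply(X[, active, drop = FALSE], 2, stats::sd)
    beta_std <- b * sdx / stats::sd(y)
    retained <- data.frame(predictor = active, beta = unname(b),
                           standardized_beta = unname(beta_std),
                           p_value = unname(pv), stringsAsFactors = FALSE)
    fs <- sm$fstatistic
    model_p <- unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    f_stat <- unname(fs[1]); df <- unname(c(fs[2], fs[3]))
  } else {
    retained <- data.frame(predictor = character(), beta = numeric(),
                           standardized_beta = numeric(), p_value = numeric(),
                           stringsAsFactors = FALSE)
    f_stat <- NA_real_; df <- c(0, n - 1L); model_p <- NA_real_
  }
  structure(list(retained = retained, excluded = excluded,
                 adj_r2 = sm$adj.r.squared, f_stat = f_stat, df = df,
                 model_p = model_p, n = n, threshold = threshold),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, adj R^2 = %.3f, F(%g, %g) = %.3g, model p = %.4g\n",
              x$n, x$adj_r2, x$df[1], x$df[2], x$f_stat, x$model_p))
  if (nrow(x$retained)) {
    cat("  retained:\n")
    for (i in seq_len(nrow(x$retained))) {
      cat(sprintf("    %-28s beta* = %+.3f  p = %.4f\n",
                  x$retained$predictor[i], x$retained$standardized_beta[i],
                  x$retained$p_value[i]))
    }
  }
  if (nrow(x$excluded)) {
    cat("  excluded:",
        paste(sprintf("%s (p = %.3f)", x$excluded$predictor,
                      x$excluded$p_value_at_exclusion), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` comparisons; with the default `alpha = 0.05` and
#' three executive-function aspects this gives 0.0167 (reported at 4
#' decimals in summaries).
#'
#' @param alpha Family-wise level, in (0, 1).
#' @param m Number of comparisons, `>= 1`.
#' @return Corrected threshold (full precision; round for display).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3L) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("alpha must be a single number in (0, 1)")
  }
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be an integer >= 1")
  alpha / m
}
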