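#' Normality-gated two-group comparison
#'
#' Compares a continuous marker between two groups with the test chosen by
#' a Shapiro-Wilk normality gate at the 0.05 level applied to each group:
#' if both groups pass, Student's t-test; otherwise the Mann-Whitney U
#' test. Summaries are reported as mean +/- sd for normal data and as
#' median (IQR) otherwise, mirroring conventional clinical tables.
#'
#' @param values per-lesion marker values.
#' @param labels two-level group labels, same length as `values`.
#' @param test `"auto"` applies the normality gate; `"t"` or
#'   `"mann-whitney"` force a test.
#' @param normal_alpha significance level of the normality gate.
#' @return A `group_comparison` list: `test_used`, `p_value`, `normal`,
#'   per-group `summaries` (n, mean, sd, median, iqr), and `summary_type`.
#' @export
compare_groups <- function(values, labels,
                           test = c("auto", "t", "mann-whitney"),
                           normal_alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(length(values) == length(labels))
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels[keep])
  lev <- unique(labels)
  if (length(lev) != 2L) stop("`labels` must have exactly two groups", call. = FALSE)
  g1 <- values[labels == lev[1]]
  g2 <- values[labels == lev[2]]
  if (length(g1) < 3L || length(g2) < 3L) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  sw <- function(x) {
    if (stats::sd(x) == 0) return(0)  # constant group: clearly non-normal gate
    stats::shapiro.test(x)$p.value
  }
  normal <- sw(g1) > normal_alpha && sw(g2) > normal_alpha
  use_t <- switch(test, auto = normal, t = TRUE, `mann-whitney` = FALSE)
  p <- if (use_t) {
    stats::t.test(g1, g2, var.equal = TRUE)$p.value
  } else {
    stats::wilcox.test(g1, g2, exact = NULL)$p.value
  }
  summaries <- data.frame(
    group = lev,
    n = c(length(g1), length(g2)),
    mean = c(mean(g1), mean(g2)),
    sd = c(stats::sd(g1), stats::sd(g2)),
    median = c(stats::median(g1), stats::median(g2)),
    iqr = c(stats::IQR(g1), stats::IQR(g2))
  )
  structure(list(test_used = if (use_t) "t-test" else "mann-whitney",
                 p_value = p, normal = normal,
                 summary_type = if (normal) "mean_sd" else "median_iqr",
                 summaries = summaries),
            class = "group_comparison")
}

#' Tie-corrected Mann-Whitney AUC
#'
#' The empirical AUC computed directly from the Mann-Whitney U statistic
#' with midranks, \eqn{AUC = U / (n_1 n_2)}, where tied pairs count one
#' half. This is algebraically identical to the trapezoidal area under the
#' empirical ROC curve and provides an independent code path for checking
#' [roc_analysis()], as well as a fast AUC for large simulation loops.
#'
#' @param scores marker values.
#' @param labels binary class labels.
#' @param positive label of the positive class.
#' @param direction `"higher"` if larger scores indicate the positive
#'   class, `"lower"` otherwise.
#' @return The AUC (scalar in `[0, 1]`).
#' @export
auc_mann_whitney <- function(scores, labels, positive,
                             direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  is_pos <- as.character(labels) == positive
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks: tied pairs contribute 1/2
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  if (direction == "lower") 1 - auc else auc
}

# resolve a pROC direction string: "<" = higher predictor indicates the case
.roc_direction <- function(direction) {
  switch(direction, auto = "auto", higher = "<", lower = ">",
         stop("`direction` must be auto/higher/lower", call. = FALSE))
}

#' ROC analysis with a Youden-index operating point
#'
#' Empirical ROC curve of a continuous marker for a binary pathology label,
#' with the area under the curve and its 95% DeLong confidence interval
#' (via pROC), and the operating point maximising the Youden index
#' J = sensitivity + specificity - 1. Candidate cutoffs are placed midway
#' between adjacent distinct marker values; when several cutoffs share the
#' maximal J, the one with the highest sensitivity is reported. Sensitivity,
#' specificity and accuracy are given in percent at that cutoff.
#'
#' @param scores marker values.
#' @param labels binary class labels.
#' @param positive label of the positive class (e.g. `"high"` grade).
#' @param direction `"higher"` if larger scores indicate the positive
#'   class, `"lower"` if smaller do (typical for diffusion markers),
#'   `"auto"` to orient so that AUC >= 0.5.
#' @return A `roc_result` list: `auc`, `ci_low`, `ci_high`, `cutoff`,
#'   `sensitivity`, `specificity`, `accuracy` (percent), `youden`,
#'   `direction` (resolved), `positive`, `n_pos`, `n_neg` and the full
#'   `coords` (threshold, sensitivity, specificity).
#' @export
roc_analysis <- function(scores, labels, positive,
                         direction = c("auto", "higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as.character(labels)
  if (missing(positive)) stop("`positive` class label is required", call. = FALSE)
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- pROC::roc(response = is_pos, predictor = scores,
                 levels = c(FALSE, TRUE), direction = .roc_direction(direction),
                 quiet = TRUE)
  auc <- as.numeric(r$auc)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  resolved <- if (r$direction == "<") "higher" else "lower"

  su <- sort(unique(scores))
  cand <- c(-Inf, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2, Inf)
  stats_at <- function(thr) {
    pred_pos <- if (resolved == "higher") scores > thr else scores < thr
    tp <- sum(pred_pos & is_pos); tn <- sum(!pred_pos & !is_pos)
    c(sens = tp / n_pos, spec = tn / n_neg,
      acc = (tp + tn) / (n_pos + n_neg))
  }
  m <- vapply(cand, stats_at, c(sens = 0, spec = 0, acc = 0))
  j <- unname(m["sens", ] + m["spec", ] - 1)
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(m["sens", best])]
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[3],
                 cutoff = cand[best], youden = j[best],
                 sensitivity = unname(100 * m["sens", best]),
                 specificity = unname(100 * m["spec", best]),
                 accuracy = unname(100 * m["acc", best]),
                 direction = resolved, positive = positive,
                 n_pos = n_pos, n_neg = n_neg,
                 coords = data.frame(threshold = cand,
                                     sensitivity = m["sens", ],
                                     specificity = m["spec", ])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g (%s = positive '%s')\n",
    x$auc, x$ci_low, x$ci_high, x$cutoff, x$direction, x$positive))
  cat(sprintf("  sensitivity %.2f%%, specificity %.2f%%, accuracy %.2f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Paired DeLong comparison of two AUCs
#'
#' DeLong's nonparametric test for the difference between the AUCs of two
#' markers measured on the same lesions. When the markers are rank-identical
#' the variance of the AUC difference is zero and the comparison is
#' degenerate: the difference is 0 and p is reported as 1 with a flag.
#'
#' @param scores_a,scores_b paired marker values.
#' @param labels binary class labels.
#' @param positive label of the positive class.
#' @param direction orientation passed to the underlying ROC fits.
#' @return List with `auc_a`, `auc_b`, `auc_diff`, `p_value`, `degenerate`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, positive,
                           direction = c("auto", "higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  labels <- as.character(labels)
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) stop("both classes must be present", call. = FALSE)
  dirchar <- .roc_direction(direction)
  ra <- pROC::roc(is_pos, scores_a, levels = c(FALSE, TRUE),
                  direction = dirchar, quiet = TRUE)
  rb <- pROC::roc(is_pos, scores_b, levels = c(FALSE, TRUE),
                  direction = dirchar, quiet = TRUE)
  diff <- as.numeric(ra$auc) - as.numeric(rb$auc)
  if (identical(rank(scores_a), rank(scores_b))) {
    # rank-identical markers: the AUC difference has zero variance
    return(list(auc_a = as.numeric(ra$auc), auc_b = as.numeric(rb$auc),
                auc_diff = 0, p_value = 1, degenerate = TRUE))
  }
  tt <- suppressWarnings(
    tryCatch(pROC::roc.test(ra, rb, method = "delong", paired = TRUE),
             error = function(e) NULL))
  p <- if (is.null(tt)) NaN else tt$p.value
  degenerate <- !is.finite(p)
  if (degenerate) p <- 1
  list(auc_a = as.numeric(ra$auc), auc_b = as.numeric(rb$auc),
       auc_diff = diff, p_value = p, degenerate = degenerate)
}

#' Univariate selection and multivariate logistic combination
#'
#' Fits a univariate logistic regression of the outcome on each candidate
#' marker (reporting the Wald p-value), selects the markers significant at
#' `select_alpha`, and combines the selected markers in one multivariate
#' logistic model. The combined score is the fitted linear predictor, which
#' preserves the multivariate model's ROC behaviour. The fit is
#' deterministic. Perfect separation is flagged (`converged = FALSE`) and
#' the score from the final iterate is still returned; rank-deficient
#' feature sets (duplicated markers) are flagged via `collinear` and the
#' aliased columns are dropped by the fit.
#'
#' @param features data.frame (or matrix) of candidate markers, one column
#'   per marker, no missing values.
#' @param labels binary class labels.
#' @param positive label of the positive class.
#' @param select_alpha univariate inclusion threshold.
#' @return List with `univariate` (feature, estimate, p_value), `selected`,
#'   `model` (the multivariate `glm`, or NULL when nothing is selected),
#'   `score` (per-lesion linear predictor, or NULL), `converged`,
#'   `collinear`.
#' @export
logistic_combine <- function(features, labels, positive, select_alpha = 0.05) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels), !anyNA(features))
  if (nrow(features) < 10L) stop("at least 10 lesions are required", call. = FALSE)
  y <- as.integer(as.character(labels) == positive)
  fit_glm <- function(df) {
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = cbind(y = y, df), family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    list(fit = fit, separated = sep)
  }
  uni <- do.call(rbind, lapply(names(features), function(nm) {
    f <- fit_glm(features[nm])
    co <- summary(f$fit)$coefficients
    data.frame(feature = nm, estimate = co[2, 1], p_value = co[2, 4],
               separated = f$separated)
  }))
  # Wald p-values collapse under (quasi-)separation even though the
  # association is then maximal, so a separated marker is admitted as well
  selected <- uni$feature[uni$p_value < select_alpha | uni$separated]
  if (!length(selected)) {
    return(list(univariate = uni, selected = character(0), model = NULL,
                score = NULL, converged = TRUE, collinear = FALSE))
  }
  mv <- fit_glm(features[selected])
  collinear <- anyNA(stats::coef(mv$fit))
  score <- as.numeric(stats::predict(mv$fit, type = "link"))
  list(univariate = uni, selected = selected, model = mv$fit, score = score,
       converged = !mv$separated, collinear = collinear)
}

#' Full group-level discrimination analysis of a cohort
#'
#' Orchestrates, for each requested pathology contrast (grade: low vs high;
#' variant: pUC vs VH), the per-parameter two-group comparison and ROC
#' analysis, the univariate/multivariate logistic combination of the CTRW
#' parameters (D, alpha, beta; admitted when univariately significant), the
#' ROC of the combined score, and the DeLong comparison of the combined
#' score against ADC.
#'
#' @param cohort a `cohort_table` (or data.frame) with label columns
#'   `grade`/`variant` and averaged parameter columns `adc`, `D`, `alpha`,
#'   `beta`.
#' @param contrasts which contrasts to analyse.
#' @param params parameter columns to analyse individually.
#' @return A `study_report` list, one entry per contrast, each containing
#'   `comparisons`, `roc` (per-parameter + combined `roc_result`s),
#'   `logistic`, and `delong_combined_vs_adc`.
#' @seealso [write_study_report()]
#' @export
run_study_analysis <- function(cohort, contrasts = c("grade", "variant"),
                               params = c("adc", "D", "alpha", "beta")) {
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  missing_cols <- setdiff(c(contrasts, params), names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ctrw_feats <- intersect(c("D", "alpha", "beta"), params)
  report <- lapply(contrasts, function(con) {
    positive <- if (con == "grade") "high" else "VH"
    labels <- cohort[[con]]
    comparisons <- lapply(params, function(p) compare_groups(cohort[[p]], labels))
    names(comparisons) <- params
    roc <- lapply(params, function(p) {
      roc_analysis(cohort[[p]], labels, positive = positive, direction = "auto")
    })
    names(roc) <- params
    lg <- logistic_combine(cohort[ctrw_feats], labels, positive = positive)
    combined <- NULL
    delong <- NULL
    if (!is.null(lg$score)) {
      combined <- roc_analysis(lg$score, labels, positive = positive,
                               direction = "auto")
      delong <- delong_compare(lg$score, cohort[["adc"]], labels,
                               positive = positive, direction = "auto")
      roc[[paste(lg$selected, collapse = "+")]] <- combined
    }
    list(contrast = con, positive = positive, comparisons = comparisons,
         roc = roc, logistic = lg, delong_combined_vs_adc = delong)
  })
  names(report) <- contrasts
  structure(report, class = "study_report")
}

# Format one contrast's comparison table (clinical-table style strings).
.table_comparisons <- function(entry) {
  do.call(rbind, lapply(names(entry$comparisons), function(p) {
    cmp <- entry$comparisons[[p]]
    s <- cmp$summaries
    fmt <- function(i) {
      if (cmp$summary_type == "mean_sd") {
        sprintf("%.3f +/- %.3f", s$mean[i], s$sd[i])
      } else {
        sprintf("%.3f (%.3f)", s$median[i], s$iqr[i])
      }
    }
    data.frame(parameter = p, group1 = s$group[1], summary1 = fmt(1),
               group2 = s$group[2], summary2 = fmt(2),
               test = cmp$test_used, p_value = cmp$p_value)
  }))
}

# Format one contrast's diagnostic-performance table.
.table_roc <- function(entry) {
  do.call(rbind, lapply(names(entry$roc), function(p) {
    r <- entry$roc[[p]]
    data.frame(parameter = p, auc = r$auc, ci_low = r$ci_low,
               ci_high = r$ci_high, cutoff = r$cutoff,
               sensitivity_pct = round(r$sensitivity, 2),
               specificity_pct = round(r$specificity, 2),
               accuracy_pct = round(r$accuracy, 2))
  }))
}

#' Write a study report to disk
#'
#' Writes `report.json` (machine readable), one comparison and one
#' diagnostic-performance CSV per contrast, and the ROC curve coordinates
#' of every analysed marker for plotting.
#'
#' @param report a `study_report` from [run_study_analysis()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json <- lapply(report, function(entry) {
    list(contrast = entry$contrast, positive = entry$positive,
         comparisons = .table_comparisons(entry),
         roc = .table_roc(entry),
         logistic = list(univariate = entry$logistic$univariate,
                         selected = entry$logistic$selected,
                         converged = entry$logistic$converged,
                         collinear = entry$logistic$collinear),
         delong_combined_vs_adc = entry$delong_combined_vs_adc)
  })
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  for (con in names(report)) {
    utils::write.csv(.table_comparisons(report[[con]]),
                     file.path(dir, sprintf("comparison_%s.csv", con)),
                     row.names = FALSE)
    utils::write.csv(.table_roc(report[[con]]),
                     file.path(dir, sprintf("performance_%s.csv", con)),
                     row.names = FALSE)
    coords <- do.call(rbind, lapply(names(report[[con]]$roc), function(p) {
      cbind(parameter = p, report[[con]]$roc[[p]]$coords)
    }))
    utils::write.csv(coords,
                     file.path(dir, sprintf("roc_coords_%s.csv", con)),
                     row.names = FALSE)
  }
  invisible(dir)
}
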