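# independent DeLong computation from placement values, used as an oracle
delong_manual <- function(a, b, is_pos) {
  placements <- function(s) {
    pos <- s[is_pos]; neg <- s[!is_pos]
    v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0.0)
    v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)), 0.0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(a); pb <- placements(b)
  m <- sum(is_pos); n <- sum(!is_pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(diff = pa$auc - pb$auc, p = 2 * stats::pnorm(-abs(z)))
}

test_that("the normality gate picks the test and the summary format", {
  set.seed(3)
  vals <- c(rnorm(30, 10, 1), rnorm(30, 12, 1))
  labs <- rep(c("a", "b"), each = 30)
  cmp <- compare_groups(vals, labs)
  expect_identical(cmp$test_used, "t-test")
  expect_identical(cmp$summary_type, "mean_sd")
  skewed <- c(exp(rnorm(40, 0, 2)), exp(rnorm(40, 1, 2)))
  cmp2 <- compare_groups(skewed, rep(c("a", "b"), each = 40))
  expect_identical(cmp2$test_used, "mann-whitney")
  expect_identical(cmp2$summary_type, "median_iqr")
})

test_that("forced Mann-Whitney reproduces the exact small-sample p-value", {
  # all 20 label assignments of {1..6}: U = 0 has probability 1/20 per tail
  cmp <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3),
                        test = "mann-whitney")
  expect_equal(cmp$p_value, 0.1)
})

test_that("both tests are location-shift invariant", {
  set.seed(11)
  vals <- rnorm(40)
  labs <- rep(c("a", "b"), 20)
  for (tt in c("t", "mann-whitney")) {
    p0 <- compare_groups(vals, labs, test = tt)$p_value
    p1 <- compare_groups(vals + 17.3, labs, test = tt)$p_value
    expect_equal(p0, p1, tolerance = 1e-12)
  }
  expect_error(compare_groups(vals, rep("a", 40)), "two groups")
})

test_that("label-shuffled halves of one sample give unremarkable p-values", {
  set.seed(13)
  vals <- rnorm(40)
  p <- compare_groups(vals, sample(rep(c("a", "b"), 20)))$p_value
  expect_gt(p, 1e-4)
})

test_that("perfect separation gives AUC 1 and a perfect operating point", {
  r <- roc_analysis(c(1, 2, 3, 4), c("n", "n", "p", "p"), positive = "p",
                    direction = "higher")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$accuracy, 100)
  expect_true(r$cutoff > 2 && r$cutoff < 3)
})

test_that("chance-level markers give AUC 1/2 and orientation flips AUC", {
  # concordant pairs: (1,3),(1,2),(4,3),(4,2) -> 2 of 4
  r <- roc_analysis(c(3, 1, 2, 4), c("n", "p", "n", "p"), positive = "p",
                    direction = "higher")
  expect_equal(r$auc, 0.5)
  set.seed(17)
  s <- rnorm(60); lab <- rep(c("n", "p"), 30)
  up <- roc_analysis(s, lab, positive = "p", direction = "higher")
  dn <- roc_analysis(s, lab, positive = "p", direction = "lower")
  expect_equal(up$auc, 1 - dn$auc, tolerance = 1e-12)
})

test_that("AUC equals the tie-corrected U statistic on arbitrary data", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    s <- sample(1:8, n, replace = TRUE) + sample(c(0, 0, 0.5), n, replace = TRUE)
    lab <- sample(c("n", "p"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    r <- roc_analysis(s, lab, positive = "p", direction = "higher")
    expect_equal(r$auc, auc_mann_whitney(s, lab, positive = "p"),
                 tolerance = 1e-12)
  }
})

test_that("no threshold beats the reported Youden point", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    s <- round(rnorm(n, rep(c(0, 0.8), length.out = n)), 1)  # with ties
    lab <- rep(c("n", "p"), length.out = n)
    r <- roc_analysis(s, lab, positive = "p", direction = "higher")
    is_pos <- lab == "p"
    for (thr in c(-Inf, sort(unique(s)), Inf)) {
      sens <- mean(s[is_pos] > thr)
      spec <- mean(s[!is_pos] <= thr)
      expect_lte(sens + spec - 1, r$youden + 1e-12)
    }
  }
})

test_that("DeLong comparison matches an independent placement-value oracle", {
  set.seed(29)
  t0 <- rnorm(81)
  a <- t0 + rnorm(81, 0, 0.8)
  b <- t0 + rnorm(81, 0, 0.8)
  lab <- c(rep("low", 15), rep("high", 66))
  got <- delong_compare(a, b, lab, positive = "high", direction = "higher")
  ref <- delong_manual(a, b, lab == "high")
  expect_equal(got$auc_diff, ref$diff, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p, tolerance = 1e-9)
})

test_that("rank-identical markers are a degenerate DeLong comparison", {
  set.seed(31)
  s <- rnorm(40); lab <- rep(c("n", "p"), 20)
  same <- delong_compare(s, s, lab, positive = "p")
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  mono <- delong_compare(s, exp(2 * s) - 5, lab, positive = "p")
  expect_equal(mono$auc_diff, 0)
})

test_that("logistic combination of one feature preserves its ROC", {
  set.seed(37)
  x <- rnorm(60)
  y <- ifelse(x + rnorm(60, 0, 0.8) > 0, "p", "n")
  lg <- logistic_combine(data.frame(x = x), y, positive = "p")
  expect_identical(lg$selected, "x")
  r_raw <- roc_analysis(x, y, positive = "p", direction = "higher")
  r_comb <- roc_analysis(lg$score, y, positive = "p", direction = "higher")
  expect_equal(r_comb$auc, r_raw$auc, tolerance = 1e-12)
})

test_that("duplicated features are flagged collinear without changing the score", {
  set.seed(41)
  x <- rnorm(60)
  y <- ifelse(x + rnorm(60, 0, 0.8) > 0, "p", "n")
  lg1 <- logistic_combine(data.frame(x = x), y, positive = "p")
  lg2 <- logistic_combine(data.frame(x = x, x2 = x), y, positive = "p")
  expect_true(lg2$collinear)
  expect_equal(lg2$score, lg1$score, tolerance = 1e-8)
})

test_that("perfect separation is flagged but still yields a usable score", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c("n", "p"), each = 20)
  lg <- logistic_combine(data.frame(x = x), y, positive = "p")
  expect_false(lg$converged)
  expect_length(lg$score, 40)
  r <- roc_analysis(lg$score, y, positive = "p", direction = "higher")
  expect_equal(r$auc, 1)
})

test_that("univariate logistic holds its nominal size under the null", {
  set.seed(43)
  n_rep <- 400
  hits <- 0
  lab <- c(rep("low", 15), rep("high", 66))
  for (i in seq_len(n_rep)) {
    lg <- logistic_combine(data.frame(x = rnorm(81)), lab, positive = "high")
    hits <- hits + (lg$univariate$p_value[1] < 0.05)
  }
  rate <- hits / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("the full study analysis populates both contrasts", {
  coh <- generate_cohort(seed = 6)
  rep_ <- run_study_analysis(coh)
  expect_named(rep_, c("grade", "variant"))
  for (con in names(rep_)) {
    entry <- rep_[[con]]
    expect_named(entry$comparisons, c("adc", "D", "alpha", "beta"))
    expect_gte(length(entry$roc), 5)  # four parameters + combined
    expect_gte(length(entry$logistic$selected), 1)
    expect_true(is.finite(entry$delong_combined_vs_adc$p_value))
  }
  expect_true(all(c("D", "alpha") %in% rep_$grade$logistic$selected))
  # the combined CTRW model should not trail its best component by much
  g <- rep_$grade$roc
  comb_name <- paste(rep_$grade$logistic$selected, collapse = "+")
  expect_gt(g[[comb_name]]$auc, max(g$D$auc, g$alpha$auc) - 0.02)
  expect_error(run_study_analysis(coh[, setdiff(names(coh), "grade")]),
               "lacks columns")
})

test_that("a marker with no group difference yields null comparisons", {
  coh <- generate_cohort(seed = 8)
  # identical alpha value distribution in both groups
  v <- c(0.75, 0.82, 0.89)
  coh$alpha[coh$grade == "low"] <- rep(v, each = 5)
  coh$alpha[coh$grade == "high"] <- rep(v, each = 22)
  cmp <- compare_groups(coh$alpha, coh$grade)
  expect_gt(cmp$p_value, 0.5)
  r <- roc_analysis(coh$alpha, coh$grade, positive = "high", direction = "lower")
  expect_equal(r$auc, 0.5, tolerance = 1e-12)
})

test_that("study reports are written in machine- and human-readable form", {
  coh <- generate_cohort(seed = 10)
  rep_ <- run_study_analysis(coh, contrasts = "grade")
  dir <- withr::local_tempdir()
  write_study_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "comparison_grade.csv")))
  expect_true(file.exists(file.path(dir, "performance_grade.csv")))
  expect_true(file.exists(file.path(dir, "roc_coords_grade.csv")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js[[1]]$contrast, "grade")
  perf <- read.csv(file.path(dir, "performance_grade.csv"))
  expect_equal(nrow(perf), 5)
})
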