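test_that("noiseless phantom equals the forward model exactly", {
  spec <- phantom_spec(dim = c(6, 6, 1), snr = Inf, seed = 5)
  ph <- generate_phantom(spec)
  sch <- spec$scheme
  sig <- ph$series$signal
  for (lab in 1:4) {
    vox <- which(ph$labels == lab)[1]
    idx <- arrayInd(vox, dim(ph$labels))
    row <- spec$tissue[spec$tissue$label == lab, ]
    expected <- ctrw_signal(ctrw_params(row$D, row$alpha, row$beta), row$S0, sch$b)
    expect_equal(as.numeric(sig[idx[1], idx[2], idx[3], ]), expected,
                 tolerance = 1e-12)
  }
})

test_that("phantom generation is deterministic under its seed", {
  s1 <- generate_phantom(phantom_spec(dim = c(8, 8, 1), snr = 30, seed = 11))
  s2 <- generate_phantom(phantom_spec(dim = c(8, 8, 1), snr = 30, seed = 11))
  s3 <- generate_phantom(phantom_spec(dim = c(8, 8, 1), snr = 30, seed = 12))
  expect_identical(s1$series$signal, s2$series$signal)
  expect_false(identical(s1$series$signal, s3$series$signal))
})

test_that("observed magnitude matches the analytic Rician mean", {
  # ~1e5 independent single-excitation draws at b = 0, SNR 10
  tissue <- data.frame(label = 1L, D = 1e-3, alpha = 0.8, beta = 0.9, S0 = 500)
  spec <- phantom_spec(dim = c(320, 320, 1),
                       labels = array(1L, dim = c(320, 320, 1)),
                       tissue = tissue, scheme = bvalue_scheme(0, 1),
                       snr = 10, seed = 21)
  ph <- generate_phantom(spec)
  x <- as.numeric(ph$series$signal)
  analytic <- rician_mean(500, 500 / 10)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - analytic), 3 * se)
})

test_that("excitation averaging shrinks the noise like 1/sqrt(NEX)", {
  tissue <- data.frame(label = 1L, D = 1e-6, alpha = 1, beta = 1, S0 = 1000)
  sch <- bvalue_scheme(c(0, 1), c(1L, 16L))  # negligible decay between the two
  spec <- phantom_spec(dim = c(200, 200, 1),
                       labels = array(1L, dim = c(200, 200, 1)),
                       tissue = tissue, scheme = sch, snr = 20, seed = 31)
  ph <- generate_phantom(spec)
  sd1 <- sd(ph$series$signal[, , , 1])
  sd16 <- sd(ph$series$signal[, , , 2])
  expect_equal(sd1 / sd16, 4, tolerance = 0.1)
})

test_that("enrollment flow reproduces the screening counts", {
  enr <- generate_enrollment(seed = 3)
  expect_equal(nrow(enr), 107)
  expect_equal(nrow(filter_enrolled(enr)), 81)
  counts <- table(enr$exclusion_flag)
  expect_equal(as.integer(counts[c("no_pathology", "poor_quality",
                                   "small_lesion", "incomplete_pathology")]),
               c(12L, 1L, 4L, 9L))
  expect_equal(nrow(generate_enrollment(counts = c(none = 0), seed = 1)), 0)
  expect_identical(generate_enrollment(seed = 9), generate_enrollment(seed = 9))
})

test_that("default cohort reproduces the reference composition", {
  coh <- generate_cohort(seed = 2)
  expect_equal(nrow(coh), 81)
  expect_equal(sum(coh$grade == "low"), 15)
  expect_equal(sum(coh$grade == "high"), 66)
  expect_equal(sum(coh$variant == "VH"), 30)
  expect_equal(sum(coh$variant == "pUC"), 51)
  expect_equal(as.integer(table(coh$stage)[c("pTa", "pT1", "pT2", "pT3", "pT4")]),
               c(4L, 39L, 16L, 11L, 11L))
  expect_error(generate_cohort(n_pUC = 40, n_VH = 30), "n_pUC")
  expect_identical(generate_cohort(seed = 5), generate_cohort(seed = 5))
})

test_that("large-sample cohort draws match the calibrated median and IQR", {
  n_hi <- 100000
  coh <- generate_cohort(n_low = 5, n_high = n_hi, n_pUC = n_hi + 5 - 30,
                         n_VH = 30, stage_counts = c(pT1 = n_hi + 5),
                         seed = 13)
  a <- coh$alpha_true[coh$grade == "high"]
  cell <- ref_cell("high", "alpha")
  expect_lt(abs(median(a) - cell$median) / cell$median, 0.005)
  expect_lt(abs(IQR(a) - cell$iqr) / cell$iqr, 0.02)
  d <- coh$D_true[coh$grade == "high"]
  cellD <- ref_cell("high", "D")
  expect_lt(abs(median(d) - cellD$median) / cellD$median, 0.005)
  expect_lt(abs(IQR(d) - cellD$iqr) / cellD$iqr, 0.02)
})

test_that("variant-conditioned cohorts calibrate the pUC/VH cells instead", {
  n_vh <- 50000
  coh <- generate_cohort(n_low = 15, n_high = 2 * n_vh - 15,
                         n_pUC = n_vh, n_VH = n_vh,
                         stage_counts = c(pT1 = 2 * n_vh),
                         group_by = "variant", seed = 17)
  v <- coh$adc_true[coh$variant == "VH"]
  cell <- ref_cell("VH", "adc")
  expect_lt(abs(median(v) - cell$median) / cell$median, 0.01)
  expect_lt(abs(IQR(v) - cell$iqr) / cell$iqr, 0.03)
})

test_that("alpha/beta clipping is recorded and stays a small tail effect", {
  coh <- generate_cohort(seed = 4)
  rate <- attr(coh, "clip_rate")
  expect_true(is.numeric(rate) && rate >= 0 && rate < 0.05)
  expect_true(all(coh$alpha <= 1 & coh$alpha > 0))
  expect_true(all(coh$beta <= 1 & coh$beta > 0))
})

test_that("two-reader ICCs of the default cohort sit in the near-perfect band", {
  seeds <- 1:20
  ok <- vapply(seeds, function(s) {
    coh <- generate_cohort(seed = s)
    all(vapply(c("adc", "D", "alpha", "beta"), function(p) {
      icc <- interobserver_icc(coh[[paste0(p, "_r1")]], coh[[paste0(p, "_r2")]])
      icc$icc > 0.8 && icc$icc <= 1
    }, TRUE))
  }, TRUE)
  expect_gte(sum(ok), 19)
})

test_that("lognormal calibration hits its median and approximate IQR", {
  cal <- lognormal_calibration(0.783, 0.099)
  expect_equal(exp(cal$meanlog), 0.783)
  q <- qlnorm(c(0.25, 0.75), cal$meanlog, cal$sdlog)
  expect_lt(abs(diff(q) - 0.099) / 0.099, 0.002)
})
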