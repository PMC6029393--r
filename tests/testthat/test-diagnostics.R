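test_that("confusion counts cross-tabulate against the biopsy reference", {
  # 38 cases with 34 test-positive, 49 controls with 35 test-negative
  calls <- c(rep(TRUE, 34), rep(FALSE, 4), rep(TRUE, 14), rep(FALSE, 35))
  labels <- c(rep(1, 38), rep(0, 49))
  cc <- confusion_counts(calls, labels)
  expect_equal(unclass(cc)[c("tp", "fn", "tn", "fp")],
               list(tp = 34, fn = 4, tn = 35, fp = 14))
  cc2 <- confusion_counts(c(a = FALSE, b = FALSE, c = FALSE, d = FALSE,
                            e = FALSE),
                          c(a = 1, b = 1, c = 1, d = 0, e = 0))
  expect_equal(unclass(cc2)[c("tp", "fp", "tn", "fn")],
               list(tp = 0, fp = 0, tn = 2, fn = 3))
  expect_error(confusion_counts(c(x = TRUE), c(y = 1)), "mismatch")
})

test_that("predictive values match the published worked examples", {
  dre <- diagnostic_metrics(list(tp = 34, fn = 4, tn = 35, fp = 14))
  expect_equal(dre$ppv, 34 / 48)
  expect_equal(dre$npv, 35 / 39)
  expect_equal(round_half_up(dre$ppv), 0.71)
  expect_equal(round_half_up(dre$npv), 0.90)
  fv <- diagnostic_metrics(list(tp = 30, fn = 2, tn = 25, fp = 10))
  expect_equal(fv$ppv, 0.75)
  expect_equal(round_half_up(fv$npv), 0.93)
  expect_error(diagnostic_metrics(list(tp = -1, fp = 0, tn = 1, fn = 1)),
               "non-negative")
})

test_that("zero-denominator metrics are reported as undefined, never 0", {
  row <- diagnostic_metrics(list(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_true(is.na(row$sensitivity))
  expect_equal(row$specificity, 1)
  expect_true(is.na(row$ppv))
  expect_match(row$undefined, "sensitivity")
  expect_match(row$undefined, "ppv")
})

test_that("Wilson intervals reproduce the published per-assay intervals", {
  expect_equal(round_half_up(proportion_ci(23, 38)), c(low = 0.45, high = 0.74))
  expect_equal(round_half_up(proportion_ci(38, 49)), c(low = 0.64, high = 0.87))
})

test_that("interval methods agree with independent closed forms", {
  z <- qnorm(0.975)
  for (n in c(5, 10, 38, 49, 100)) {
    for (k in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      w <- proportion_ci(k, n, "wilson")
      expect_equal(unname(w), wilson_by_roots(k, n), tolerance = 1e-12)
      p <- k / n
      nm <- proportion_ci(k, n, "normal")
      expect_equal(unname(nm),
                   pmin(pmax(p + c(-1, 1) * z * sqrt(p * (1 - p) / n), 0), 1),
                   tolerance = 1e-12)
      # symmetry under swapping successes and failures
      for (m in c("wilson", "normal")) {
        lo <- proportion_ci(k, n, m)[["low"]]
        hi <- proportion_ci(n - k, n, m)[["high"]]
        expect_equal(lo, 1 - hi, tolerance = 1e-12)
      }
      # every interval contains its point estimate
      for (m in c("wilson", "normal", "clopper-pearson")) {
        ci <- proportion_ci(k, n, m)
        expect_true(ci[["low"]] <= p + 1e-12 && p <= ci[["high"]] + 1e-12)
      }
    }
  }
  expect_equal(proportion_ci(0, 10, "clopper-pearson")[["low"]], 0)
  expect_equal(proportion_ci(10, 10, "clopper-pearson")[["high"]], 1)
})

test_that("bootstrap intervals are seeded, bounded and centered", {
  ci1 <- proportion_ci(23, 38, "bootstrap", seed = 99)
  ci2 <- proportion_ci(23, 38, "bootstrap", seed = 99)
  expect_identical(ci1, ci2)
  expect_true(ci1[["low"]] >= 0 && ci1[["high"]] <= 1)
  expect_true(ci1[["low"]] <= 23 / 38 && 23 / 38 <= ci1[["high"]])
})

test_that("ppv from counts obeys the prevalence identity exactly", {
  set.seed(17)
  for (i in 1:40) {
    tp <- sample(0:30, 1); fn <- sample(0:30, 1)
    fp <- sample(0:30, 1); tn <- sample(0:30, 1)
    if (tp + fn == 0 || tn + fp == 0 || tp + fp == 0) next
    row <- diagnostic_metrics(list(tp = tp, fp = fp, tn = tn, fn = fn))
    prev <- (tp + fn) / (tp + fn + tn + fp)
    bayes <- prev * row$sensitivity /
      (prev * row$sensitivity + (1 - prev) * (1 - row$specificity))
    expect_equal(row$ppv, bayes, tolerance = 1e-12)
  }
})

test_that("threshold sweep is monotone and rebuilds the classifier row", {
  set.seed(27)
  mmat <- rand_marker_matrix(40)
  prof <- profiles_from_markers(mmat)
  clinical <- data.frame(patient_id = prof$patient_id,
                         biopsy = rep(c(1, 0), each = 20))
  sw <- threshold_sweep(prof, clinical)
  expect_equal(nrow(sw), 19)
  expect_true(all(diff(sw$sensitivity) <= 1e-12))
  expect_true(all(diff(sw$specificity) >= -1e-12))
  # independent code path: classify + confusion + metrics at threshold 6
  labels <- stats::setNames(clinical$biopsy, clinical$patient_id)
  calls <- stats::setNames(classify_sample(prof$n_positive, 6),
                           prof$patient_id)
  direct <- diagnostic_metrics(confusion_counts(calls, labels))
  row6 <- sw[sw$threshold == 6, ]
  expect_equal(row6$sensitivity, direct$sensitivity)
  expect_equal(row6$specificity, direct$specificity)
  expect_equal(row6$ppv, direct$ppv)
  expect_equal(row6$npv, direct$npv)
  expect_equal(c(row6$tp, row6$fp, row6$tn, row6$fn),
               c(direct$tp, direct$fp, direct$tn, direct$fn))
})

test_that("sweep sensitivity is 1 while the threshold is below every case", {
  mmat <- rand_marker_matrix(10) * 0
  mmat[1:5, 1:3] <- 1  # every case has exactly 3 positive markers
  prof <- profiles_from_markers(mmat)
  clinical <- data.frame(patient_id = prof$patient_id,
                         biopsy = rep(c(1, 0), times = c(5, 5)))
  sw <- threshold_sweep(prof, clinical, thresholds = 1:5)
  expect_equal(sw$sensitivity[sw$threshold <= 3], rep(1, 3))
  expect_equal(sw$sensitivity[sw$threshold > 3], rep(0, 2))
  expect_equal(sw$specificity, rep(1, 5))
})

test_that("per-assay table carries combined rows that dominate their assays", {
  co <- shared_cohort()
  prof <- cohort_profiles(co)
  tab <- assay_performance_table(prof, co$clinical)
  panel <- default_panel()
  dual <- panel$markers$marker_id[panel$markers$n_assays == 2]
  for (st in unique(tab$sample_type)) {
    sub <- tab[tab$sample_type == st, ]
    expect_equal(nrow(sub), 24 + 5)
    for (mk in dual) {
      comb <- sub[sub$label == paste(mk, "Comb."), ]
      ids <- panel$assays$assay_id[panel$assays$marker_id == mk]
      singles <- sub[sub$label %in% ids, ]
      expect_gte(comb$sensitivity, max(singles$sensitivity))
      expect_lte(comb$specificity, min(singles$specificity))
    }
  }
})

test_that("report formatting rounds half-up to two decimals", {
  tab <- diagnostic_metrics(list(tp = 34, fn = 4, tn = 35, fp = 14))
  fm <- format_diagnostics(tab)
  expect_equal(fm$ppv, 0.71)
  expect_equal(fm$npv, 0.90)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})
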