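test_that("paired difference reproduces the closed-form t oracle", {
  # identical vectors: zero difference, degenerate interval, p = 1
  r <- paired_marker_difference(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$mean_difference, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  # differences {1, 2, 3}: t = 2 * sqrt(3) on 2 df
  r <- paired_marker_difference(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$mean_difference, 2)
  expect_equal(r$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  tq <- qt(0.975, 2) * sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(c(r$ci_low, r$ci_high), 2 + c(-tq, tq), tolerance = 1e-12)
  # constant shift recovers the shift
  set.seed(3)
  x <- runif(10, 0, 15)
  r <- paired_marker_difference(x + 1.25, x)
  expect_equal(r$mean_difference, 1.25)
  expect_error(paired_marker_difference(1, 1), "at least 2")
})

test_that("paired difference table covers scores then markers, DRE minus FV", {
  co <- shared_cohort()
  prof <- cohort_profiles(co)
  tab <- paired_difference_table(prof)
  expect_equal(tab$label[1:2], c("Average methylation",
                                 "# of positive markers"))
  expect_equal(nrow(tab), 2 + 19)
  expect_true(all(tab$ci_low <= tab$mean_difference + 1e-12))
  expect_true(all(tab$mean_difference <= tab$ci_high + 1e-12))
  # sign convention: first collection minus second
  dre <- prof[prof$sample_type == "DRE", ]
  fv <- prof[prof$sample_type == "FV", ]
  common <- intersect(dre$patient_id, fv$patient_id)
  d <- dre$avg_methylation[match(common, dre$patient_id)] -
    fv$avg_methylation[match(common, fv$patient_id)]
  expect_equal(tab$mean_difference[1], mean(d))
})

test_that("exact discordant-pair test matches binomial enumeration", {
  expect_equal(methpanel:::exact_discordant_p(0, 3), 0.25)
  expect_equal(methpanel:::exact_discordant_p(0, 0), 1)
  for (b in 0:6) for (cc in 0:6) {
    expect_equal(methpanel:::exact_discordant_p(b, cc),
                 enum_mcnemar_p(b, cc), tolerance = 1e-12)
    # symmetry and balance
    expect_equal(methpanel:::exact_discordant_p(b, cc),
                 methpanel:::exact_discordant_p(cc, b))
    if (b == cc) expect_equal(methpanel:::exact_discordant_p(b, cc), 1)
  }
})

test_that("paired test comparison handles identical and discordant calls", {
  labels <- stats::setNames(c(rep(1, 28), rep(0, 32)), sprintf("P%02d", 1:60))
  calls <- stats::setNames(rep(c(TRUE, FALSE), times = c(26, 34)),
                           names(labels))
  same <- compare_paired_tests(calls, calls, labels)
  expect_equal(same$diff_sensitivity, 0)
  expect_equal(same$diff_specificity, 0)
  expect_equal(same$p_sens, 1)
  expect_equal(same$p_spec, 1)
  expect_equal(same$concordance, 1)
  # one discordant case out of 28: difference 1/28, p = 1
  calls_b <- calls
  calls_b["P27"] <- TRUE  # case called by B only
  cmp <- compare_paired_tests(calls, calls_b, labels)
  expect_equal(cmp$diff_sensitivity, -1 / 28)
  expect_equal(round(abs(cmp$diff_sensitivity), 3), 0.036)
  expect_equal(cmp$p_sens, 1)
  expect_equal(cmp$p_spec, 1)
  expect_error(compare_paired_tests(calls[-1], calls, labels), "mismatch")
})

test_that("sensitivity difference agrees with the diagnostics route", {
  set.seed(41)
  labels <- stats::setNames(rbinom(50, 1, 0.5), sprintf("Q%02d", 1:50))
  labels[1:2] <- c(1, 0)
  a <- stats::setNames(runif(50) < 0.6, names(labels))
  b <- stats::setNames(runif(50) < 0.5, names(labels))
  cmp <- compare_paired_tests(a, b, labels)
  sens <- function(calls) {
    cc <- confusion_counts(calls, labels)
    cc$tp / (cc$tp + cc$fn)
  }
  spec <- function(calls) {
    cc <- confusion_counts(calls, labels)
    cc$tn / (cc$tn + cc$fp)
  }
  expect_equal(cmp$diff_sensitivity, sens(a) - sens(b), tolerance = 1e-12)
  expect_equal(cmp$diff_specificity, spec(a) - spec(b), tolerance = 1e-12)
})

test_that("concordance counts identical calls, optionally with biopsy", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(unname(concordance(a, a)["tests"]), 1)
  expect_equal(unname(concordance(a, !a)["tests"]), 0)
  # 49 of 60 agreeing reports as 82% at whole-percent rounding
  a <- rep(TRUE, 60)
  b <- c(rep(TRUE, 49), rep(FALSE, 11))
  k <- concordance(a, b)
  expect_equal(unname(k["tests"]), 49 / 60)
  expect_equal(round_half_up(100 * k["tests"], 0), 82, ignore_attr = TRUE)
  lab <- rep(c(1, 0), 30)
  k3 <- concordance(a, b, lab)
  expect_equal(unname(k3["three_way"]), mean(a == b & a == (lab == 1)))
})

test_that("rank-sum test uses the exact branch and matches enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 6)  # ranks 1+2+3
  expect_equal(wilcoxon_rank_sum(c(1.5, 2.5), c(1.5, 2.5))$p_value, 1)
  set.seed(43)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq(1, 40, by = 0.5), n1)
    y <- sample(setdiff(seq(1, 40, by = 0.5), x), n2)
    got <- wilcoxon_rank_sum(x, y)
    expect_true(got$exact)
    expect_equal(got$p_value, enum_wilcox_p(x, y), tolerance = 1e-12)
  }
  big <- wilcoxon_rank_sum(rnorm(40), rnorm(40) + 3)
  expect_false(big$exact)
  expect_lt(big$p_value, 0.001)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Pearson correlation interval matches cor.test and closed form", {
  set.seed(47)
  for (i in 1:10) {
    n <- sample(8:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- pearson_with_ci(x, y)
    ref <- cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
  lin <- pearson_with_ci(1:10, 2 * (1:10) + 3)
  expect_equal(lin$r, 1)
  expect_true(lin$degenerate)
  expect_error(pearson_with_ci(1:10, rep(2, 10)), "zero variance")
  expect_error(pearson_with_ci(1:3, 1:3), "at least 4")
})

test_that("Fisher z interval coverage is near nominal at n = 35", {
  set.seed(53)
  rho <- 0.5
  hits <- 0
  B <- 800
  for (i in 1:B) {
    x <- rnorm(35)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(35)
    r <- cor(x, y)
    ci <- fisher_z_ci(r, 35)
    hits <- hits + (ci[["low"]] <= rho && rho <= ci[["high"]])
  }
  expect_gt(hits / B, 0.93)
  expect_lt(hits / B, 0.97)
})

test_that("group summaries use type-7 quantiles per group and statistic", {
  set.seed(59)
  mmat <- rand_marker_matrix(30, p_pos = 0.6)
  prof <- profiles_from_markers(mmat)
  clinical <- data.frame(
    patient_id = prof$patient_id,
    biopsy = rep(c(0, 1, 1), each = 10),
    capra_group = rep(c(0, 1, 2), each = 10))
  gs <- group_summaries(prof, clinical)
  expect_equal(nrow(gs), 3 * 2)  # 3 groups x 2 statistics, one sample type
  expect_true(all(gs$min <= gs$q1 & gs$q1 <= gs$median &
                    gs$median <= gs$q3 & gs$q3 <= gs$max))
  g1 <- gs[gs$group == 1 & gs$statistic == "n_positive", ]
  v <- prof$n_positive[match(sprintf("S%03d", 11:20), prof$patient_id)]
  expect_equal(g1$median, unname(quantile(v, 0.5, type = 7)))
  expect_equal(g1$q1, unname(quantile(v, 0.25, type = 7)))
  expect_equal(g1$mean, mean(v))
  # a group whose counts center on 11 reports median 11
  m2 <- mmat; m2[1:10, ] <- 0; m2[1:10, 1:11] <- 2
  prof2 <- profiles_from_markers(m2)
  gs2 <- group_summaries(prof2, clinical)
  expect_equal(gs2$median[gs2$group == 0 & gs2$statistic == "n_positive"], 11)
  # single-member group: all quantiles equal the value
  cl3 <- clinical; cl3$capra_group <- c(rep(0, 29), 2)
  gs3 <- group_summaries(prof, cl3)
  one <- gs3[gs3$group == 2 & gs3$statistic == "n_positive", ]
  expect_equal(one$min, one$max)
  expect_equal(one$median, one$mean)
})
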