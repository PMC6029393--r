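#' Within-subject paired difference for one marker
#'
#' Mean of the per-patient differences (first collection minus second,
#' conventionally DRE minus FV), with a paired t-test p-value and t-based
#' 95% confidence interval.
#'
#' @param x,y numeric levels paired on patient (e.g. DRE and FV), equal
#'   length; named vectors are aligned by patient id.
#' @param label marker (or score) name carried into the result.
#' @param alpha two-sided error rate.
#' @return one-row data frame: `label`, `n_pairs`, `mean_difference`,
#'   `ci_low`, `ci_high`, `p_value`, `degenerate` (TRUE when the
#'   differences have zero variance so the interval collapses).
#' @examples
#' paired_marker_difference(c(2, 4, 6), c(1, 2, 3))
#' @export
paired_marker_difference <- function(x, y, label = NA_character_,
                                     alpha = 0.05) {
  al <- align_by_patient(x, y, xname = "x", lname = "y")
  d <- as.numeric(al$x) - as.numeric(al$labels)
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stopf("need at least 2 complete pairs, got %d", n)
  m <- mean(d); s <- stats::sd(d)
  degenerate <- s == 0
  if (degenerate) {
    ci <- c(m, m)
    p <- if (m == 0) 1 else 0
  } else {
    tt <- stats::t.test(d, conf.level = 1 - alpha)
    ci <- as.numeric(tt$conf.int)
    p <- tt$p.value
  }
  data.frame(label = label, n_pairs = n, mean_difference = m,
             ci_low = ci[1], ci_high = ci[2], p_value = p,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Paired-difference table for markers and scores
#'
#' Builds the per-marker paired mean-difference table for patients with
#' both sample types, plus rows for the two sample scores
#' (`avg_methylation`, `n_positive`). Differences are DRE minus FV.
#'
#' @param profiles data frame from [build_profiles()] containing both
#'   sample types.
#' @param alpha two-sided error rate.
#' @return data frame of [paired_marker_difference()] rows.
#' @export
paired_difference_table <- function(profiles, alpha = 0.05) {
  markers <- attr(profiles, "markers")
  dre <- profiles[profiles$sample_type == "DRE", , drop = FALSE]
  fv <- profiles[profiles$sample_type == "FV", , drop = FALSE]
  common <- intersect(dre$patient_id, fv$patient_id)
  if (length(common) < 2)
    stopf("need at least 2 patients with both sample types")
  dre <- dre[match(common, dre$patient_id), , drop = FALSE]
  fv <- fv[match(common, fv$patient_id), , drop = FALSE]
  vars <- c("avg_methylation", "n_positive", markers)
  labels <- c("Average methylation", "# of positive markers", markers)
  out <- do.call(rbind, lapply(seq_along(vars), function(i)
    paired_marker_difference(dre[[vars[i]]], fv[[vars[i]]],
                             label = labels[i], alpha = alpha)))
  rownames(out) <- NULL
  out
}

# exact two-sided binomial p on discordant pairs (exact McNemar):
# double the smaller tail of Binomial(b + c, 1/2), capped at 1
exact_discordant_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  min(1, 2 * stats::pbinom(k, n, 0.5))
}

#' Compare two paired binary diagnostic tests
#'
#' Compares two tests applied to the same patients (e.g. the 6-of-19 rule on
#' DRE vs FV urine) against the biopsy reference. The sensitivity difference
#' is assessed among cases and the specificity difference among controls,
#' each with an exact two-sided binomial test on the discordant pairs
#' (exact McNemar: p = 1 when the discordants are balanced or absent) and a
#' paired Wald confidence interval on the difference.
#'
#' @param calls_a,calls_b logical (or 0/1) calls for tests A and B on the
#'   same patients; named vectors are aligned by patient.
#' @param labels binary biopsy labels for the same patients.
#' @param alpha two-sided error rate.
#' @return list of class `paired_test_comparison`: `n_pairs`, `n_cases`,
#'   `n_controls`, `diff_sensitivity`, `sens_ci`, `p_sens`,
#'   `diff_specificity`, `spec_ci`, `p_spec`, `concordance` (all patients),
#'   and the discordant counts per stratum.
#' @export
compare_paired_tests <- function(calls_a, calls_b, labels, alpha = 0.05) {
  b_calls <- as.logical(
    align_by_patient(calls_b, calls_a, "calls_b", "calls_a")$x)
  lab <- check_binary_labels(
    align_by_patient(labels, calls_a, "labels", "calls_a")$x)
  a <- as.logical(calls_a)
  if (anyNA(a) || anyNA(b_calls)) stopf("calls must be logical or 0/1")
  z <- stats::qnorm(1 - alpha / 2)
  stratum <- function(sel) {
    n <- sum(sel)
    b <- sum(a[sel] & !b_calls[sel])   # A positive, B negative
    c <- sum(!a[sel] & b_calls[sel])   # B positive, A negative
    diff <- if (n > 0) (b - c) / n else NA_real_
    ci <- if (n > 0) {
      half <- z * sqrt(pmax(0, (b + c) - (b - c)^2 / n)) / n
      c(diff - half, diff + half)
    } else c(NA_real_, NA_real_)
    list(n = n, b = b, c = c, diff = diff, ci = ci,
         p = exact_discordant_p(b, c))
  }
  cases <- stratum(lab == 1L)
  controls <- stratum(lab == 0L)
  structure(list(
    n_pairs = length(a), n_cases = cases$n, n_controls = controls$n,
    diff_sensitivity = cases$diff, sens_ci = cases$ci, p_sens = cases$p,
    discordant_cases = c(a_only = cases$b, b_only = cases$c),
    diff_specificity = -controls$diff, spec_ci = rev(-controls$ci),
    p_spec = controls$p,
    discordant_controls = c(a_only = controls$b, b_only = controls$c),
    concordance = mean(a == b_calls)
  ), class = "paired_test_comparison")
}

#' @export
print.paired_test_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_test_comparison>: %d pairs (%d cases / %d controls)\n",
    x$n_pairs, x$n_cases, x$n_controls))
  cat(sprintf("  diff sensitivity %.3f (%.3f, %.3f), exact p = %.3g\n",
              x$diff_sensitivity, x$sens_ci[1], x$sens_ci[2], x$p_sens))
  cat(sprintf("  diff specificity %.3f (%.3f, %.3f), exact p = %.3g\n",
              x$diff_specificity, x$spec_ci[1], x$spec_ci[2], x$p_spec))
  cat(sprintf("  concordance %.3f\n", x$concordance))
  invisible(x)
}

#' Concordance between two paired call vectors
#'
#' Fraction of patients with identical calls; with biopsy labels supplied,
#' also the three-way concordance (both tests and the biopsy agree).
#'
#' @inheritParams compare_paired_tests
#' @param labels optional binary biopsy labels.
#' @return named numeric: `tests` and, when labels are given, `three_way`.
#' @export
concordance <- function(calls_a, calls_b, labels = NULL) {
  ab <- align_by_patient(calls_a, calls_b, "calls_a", "calls_b")
  a <- as.logical(ab$x); b <- as.logical(ab$labels)
  out <- c(tests = mean(a == b))
  if (!is.null(labels)) {
    al <- align_by_patient(ab$x, labels, "calls_a", "labels")
    lab <- check_binary_labels(al$labels) == 1L
    out <- c(out, three_way = mean(a == b & a == lab))
  }
  out
}

#' Wilcoxon rank-sum test with explicit exact/approximate rule
#'
#' Rank-sum comparison of two score samples (midranks for ties). The exact
#' distribution is used when the combined sample size is at most 20 and no
#' ties are present; otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y numeric score samples.
#' @return list: `statistic` (rank sum of `x`), `U` (Mann-Whitney U of
#'   `x`), `p_value`, `exact` (logical).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic) + length(x) * (length(x) + 1) / 2,
       U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pearson's r with the Fisher z-transform interval
#' `tanh(atanh(r) +/- z_(alpha/2) / sqrt(n - 3))` and the t-test p-value on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors (pairs with missing values are dropped).
#' @param alpha two-sided error rate.
#' @return list: `r`, `ci_low`, `ci_high`, `p_value`, `n`, `degenerate`
#'   (TRUE for |r| = 1, where the interval collapses).
#' @examples
#' fisher_z_ci(0.649, 35)  # closed form from a reported r and n
#' @export
pearson_with_ci <- function(x, y, alpha = 0.05) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stopf("need at least 4 complete pairs, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in x or y; correlation undefined")
  r <- stats::cor(x, y)
  if (1 - r^2 < 1e-12) {
    r <- sign(r)
    return(list(r = r, ci_low = r, ci_high = r, p_value = 0, n = n,
                degenerate = TRUE))
  }
  ci <- fisher_z_ci(r, n, alpha)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, ci_low = ci[[1]], ci_high = ci[[2]], p_value = p, n = n,
       degenerate = FALSE)
}

#' @rdname pearson_with_ci
#' @param r a correlation coefficient in (-1, 1).
#' @param n the sample size behind `r` (must exceed 3).
#' @export
fisher_z_ci <- function(r, n, alpha = 0.05) {
  if (n <= 3) stopf("Fisher z interval requires n > 3")
  z <- stats::qnorm(1 - alpha / 2)
  half <- z / sqrt(n - 3)
  ci <- tanh(atanh(r) + c(-half, half))
  c(low = ci[1], high = ci[2])
}

#' Box-plot summaries of the sample scores by risk group
#'
#' Summarises `n_positive` and `avg_methylation` per sample type within the
#' three groups used for risk stratification: group 0 = negative biopsy,
#' group 1 = low-risk cases (CAPRA 1-2), group 2 = elevated-risk cases
#' (CAPRA >= 3). Quantiles use linear interpolation (type 7).
#'
#' @param profiles data frame from [build_profiles()].
#' @param clinical data frame with `patient_id`, `biopsy` and `capra_group`
#'   (0/1/2; controls are group 0).
#' @return data frame: `sample_type`, `group`, `statistic`, `n`, `min`,
#'   `q1`, `median`, `mean`, `q3`, `max`. Empty groups are omitted.
#' @export
group_summaries <- function(profiles, clinical) {
  idx <- match(profiles$patient_id, clinical$patient_id)
  if (anyNA(idx))
    stopf("patient(s) missing from clinical table: %s",
          paste(unique(profiles$patient_id[is.na(idx)]), collapse = ", "))
  grp <- clinical$capra_group[idx]
  if (!all(grp %in% 0:2)) stopf("capra_group must be coded 0, 1 or 2")
  rows <- list()
  for (st in sort(unique(profiles$sample_type))) {
    for (g in 0:2) {
      sel <- profiles$sample_type == st & grp == g
      if (!any(sel)) next
      for (stat in c("n_positive", "avg_methylation")) {
        v <- profiles[[stat]][sel]
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_type = st, group = g, statistic = stat, n = sum(sel),
          min = min(v), q1 = q[1], median = q[2], mean = mean(v),
          q3 = q[3], max = max(v), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
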