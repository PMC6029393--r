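#' Cross-tabulate test calls against the biopsy reference
#'
#' @param calls logical (or 0/1) test calls, named by patient when `labels`
#'   is named.
#' @param labels binary reference standard (1 = biopsy-positive case,
#'   0 = control), optionally named by patient.
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c(TRUE, TRUE, FALSE), c(1, 0, 0))
#' @export
confusion_counts <- function(calls, labels) {
  al <- align_by_patient(calls, labels)
  lab <- check_binary_labels(al$labels)
  cl <- as.logical(al$x)
  if (anyNA(cl)) stopf("calls must be logical or 0/1 without missing values")
  structure(list(tp = sum(cl & lab == 1L), fp = sum(cl & lab == 0L),
                 tn = sum(!cl & lab == 0L), fn = sum(!cl & lab == 1L)),
            class = "confusion_counts")
}

#' Confidence interval for a binomial proportion
#'
#' Methods: `wilson` (score interval, the default — it reproduces the
#' published per-assay intervals at two decimals), `normal` (Wald),
#' `clopper-pearson` (exact beta), and a seeded percentile `bootstrap`
#' (default 2000 resamples).
#'
#' @param successes,n integer counts, `0 <= successes <= n`.
#' @param method interval method.
#' @param alpha two-sided error rate (default 0.05 for a 95% interval).
#' @param seed RNG seed for the bootstrap method.
#' @param B bootstrap resamples.
#' @return numeric `c(low, high)` within `[0, 1]`, containing
#'   `successes / n`; `c(NA, NA)` when `n == 0` (undefined metric).
#' @examples
#' proportion_ci(23, 38)  # Wilson
#' @export
proportion_ci <- function(successes, n,
                          method = c("wilson", "normal", "clopper-pearson",
                                     "bootstrap"),
                          alpha = 0.05, seed = NULL, B = 2000) {
  method <- match.arg(method)
  if (n == 0) return(c(low = NA_real_, high = NA_real_))
  if (successes < 0 || successes > n)
    stopf("successes must lie in [0, n]; got %s/%s", successes, n)
  p <- successes / n
  z <- stats::qnorm(1 - alpha / 2)
  ci <- switch(method,
    wilson = {
      denom <- 1 + z^2 / n
      center <- (p + z^2 / (2 * n)) / denom
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      c(center - half, center + half)
    },
    normal = {
      half <- z * sqrt(p * (1 - p) / n)
      c(p - half, p + half)
    },
    `clopper-pearson` = c(
      if (successes == 0) 0 else stats::qbeta(alpha / 2, successes,
                                              n - successes + 1),
      if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1,
                                              n - successes)
    ),
    bootstrap = with_seed(seed, {
      phat <- stats::rbinom(B, n, p) / n
      unname(stats::quantile(phat, c(alpha / 2, 1 - alpha / 2), type = 7))
    })
  )
  ci <- pmin(pmax(ci, 0), 1)
  c(low = ci[1], high = ci[2])
}

#' Diagnostic operating characteristics with confidence intervals
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values from a 2x2 table against the biopsy reference. A metric whose
#' denominator is zero (e.g. PPV with no test-positives) is reported as
#' `NA` with the reason listed in the `undefined` column — never as 0.
#'
#' @param counts a `confusion_counts`, or a list/vector with `tp`, `fp`,
#'   `tn`, `fn`.
#' @param label row label for report tables.
#' @param sample_type optional stratum tag (`"DRE"` / `"FV"`).
#' @inheritParams proportion_ci
#' @return one-row data frame (class `diagnostic_row`): counts, the four
#'   metrics with `*_lo` / `*_hi` bounds, `ci_method`, `undefined`.
#' @examples
#' diagnostic_metrics(list(tp = 34, fn = 4, tn = 35, fp = 14))
#' @export
diagnostic_metrics <- function(counts, label = NA_character_,
                               sample_type = NA_character_,
                               method = "wilson", alpha = 0.05, seed = NULL,
                               B = 2000) {
  counts <- as.list(counts)[c("tp", "fp", "tn", "fn")]
  if (anyNA(match(c("tp", "fp", "tn", "fn"), names(counts))))
    stopf("counts must provide tp, fp, tn, fn")
  cnt <- vapply(counts, as.numeric, 0)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stopf("counts must be non-negative integers")
  tp <- cnt[["tp"]]; fp <- cnt[["fp"]]; tn <- cnt[["tn"]]; fn <- cnt[["fn"]]
  one <- function(x, n) {
    if (n == 0) list(est = NA_real_, ci = c(NA_real_, NA_real_))
    else list(est = x / n,
              ci = proportion_ci(x, n, method = method, alpha = alpha,
                                 seed = seed, B = B))
  }
  sens <- one(tp, tp + fn); spec <- one(tn, tn + fp)
  ppv <- one(tp, tp + fp);  npv <- one(tn, tn + fn)
  undef <- c(
    if (tp + fn == 0) "sensitivity" else NULL,
    if (tn + fp == 0) "specificity" else NULL,
    if (tp + fp == 0) "ppv" else NULL,
    if (tn + fn == 0) "npv" else NULL
  )
  data.frame(
    label = label, sample_type = sample_type,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens$est, sens_lo = sens$ci[1], sens_hi = sens$ci[2],
    specificity = spec$est, spec_lo = spec$ci[1], spec_hi = spec$ci[2],
    ppv = ppv$est, ppv_lo = ppv$ci[1], ppv_hi = ppv$ci[2],
    npv = npv$est, npv_lo = npv$ci[1], npv_hi = npv$ci[2],
    ci_method = method,
    undefined = if (length(undef)) paste(undef, collapse = ",")
                else NA_character_,
    stringsAsFactors = FALSE
  )
}

# labels per patient for one sample type, from a clinical table
.labels_for <- function(profiles, clinical, sample_type) {
  sel <- profiles$sample_type == sample_type
  ids <- profiles$patient_id[sel]
  idx <- match(ids, clinical$patient_id)
  if (anyNA(idx))
    stopf("patient(s) missing from clinical table: %s",
          paste(ids[is.na(idx)], collapse = ", "))
  stats::setNames(check_binary_labels(clinical$biopsy[idx]), ids)
}

#' Per-assay and per-marker performance table
#'
#' One row per assay and sample type using the level > 0 positivity rule,
#' plus a combined (`Comb.`) row per dual-assay marker using the merged
#' marker level — the union rule, under which combined sensitivity is at
#' least each individual assay's and combined specificity at most each
#' individual's.
#'
#' @param profiles data frame from [build_profiles()].
#' @param clinical data frame with `patient_id` and binary `biopsy`.
#' @param panel a `meth_panel`.
#' @inheritParams proportion_ci
#' @return data frame of [diagnostic_metrics()] rows; `label` is the assay
#'   id or `"<marker> Comb."`.
#' @export
assay_performance_table <- function(profiles, clinical,
                                    panel = default_panel(),
                                    method = "wilson", alpha = 0.05,
                                    seed = NULL) {
  amat <- attr(profiles, "assay_levels")
  if (is.null(amat)) stopf("profiles lack assay levels; use build_profiles()")
  mmat <- profile_marker_matrix(profiles)
  dual <- panel$markers$marker_id[panel$markers$n_assays == 2]
  rows <- list()
  for (st in sort(unique(profiles$sample_type))) {
    sel <- profiles$sample_type == st
    labels <- .labels_for(profiles, clinical, st)
    for (a in panel$assays$assay_id) {
      cc <- confusion_counts(amat[sel, a] > 0, unname(labels))
      rows[[length(rows) + 1L]] <-
        diagnostic_metrics(cc, label = a, sample_type = st, method = method,
                           alpha = alpha, seed = seed)
    }
    for (mk in dual) {
      cc <- confusion_counts(mmat[sel, mk] > 0, unname(labels))
      rows[[length(rows) + 1L]] <-
        diagnostic_metrics(cc, label = paste(mk, "Comb."), sample_type = st,
                           method = method, alpha = alpha, seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Operating characteristics at every marker-count threshold
#'
#' Sweeps the decision rule "test-positive when at least t of the panel's
#' markers are methylated" over `thresholds`, reporting the full 2x2-derived
#' metrics per threshold and sample type. Sensitivity is non-increasing and
#' specificity non-decreasing in the threshold by construction.
#'
#' @param profiles data frame from [build_profiles()].
#' @param clinical data frame with `patient_id` and binary `biopsy`.
#' @param thresholds integer thresholds to sweep (default 1:19).
#' @inheritParams proportion_ci
#' @return data frame of [diagnostic_metrics()] rows with an extra
#'   `threshold` column; `label` is `">= t of <n>"`.
#' @export
threshold_sweep <- function(profiles, clinical, thresholds = 1:19,
                            method = "wilson", alpha = 0.05, seed = NULL) {
  mk <- attr(profiles, "markers")
  nm <- if (is.null(mk)) 19L else length(mk)
  rows <- list()
  for (st in sort(unique(profiles$sample_type))) {
    sel <- profiles$sample_type == st
    labels <- .labels_for(profiles, clinical, st)
    npos <- profiles$n_positive[sel]
    for (t in thresholds) {
      cc <- confusion_counts(classify_sample(npos, t), unname(labels))
      row <- diagnostic_metrics(cc, label = sprintf(">= %d of %d", t, nm),
                                sample_type = st, method = method,
                                alpha = alpha, seed = seed)
      row$threshold <- t
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a diagnostics table for report output
#'
#' Rounds point estimates and interval bounds to two decimals (half-up, the
#' convention of the published tables); machine-readable outputs keep full
#' precision.
#'
#' @param tab data frame of [diagnostic_metrics()] rows.
#' @param digits decimal places.
#' @return data frame with rounded metric columns.
#' @export
format_diagnostics <- function(tab, digits = 2) {
  num <- intersect(c("sensitivity", "sens_lo", "sens_hi", "specificity",
                     "spec_lo", "spec_hi", "ppv", "ppv_lo", "ppv_hi",
                     "npv", "npv_lo", "npv_hi"), names(tab))
  tab[num] <- lapply(tab[num], round_half_up, digits = digits)
  tab
}
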