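#' Empirical AUC by tie-corrected pair counting
#'
#' The area under the empirical ROC curve equals the Mann-Whitney
#' probability that a random case outscores a random control, with ties
#' counted half: `AUC = (#{case > control} + 0.5 * #{ties}) / (n1 * n0)`.
#' Computed via midranks in O(n log n).
#'
#' @param scores numeric scores, higher = more cancer-like; named by patient
#'   when `labels` is named.
#' @param labels binary reference (1 = case, 0 = control).
#' @return AUC in `[0, 1]`.
#' @examples
#' empirical_auc(c(3, 5, 1, 4), c(1, 1, 0, 0))  # 0.75
#' @export
empirical_auc <- function(scores, labels) {
  al <- align_by_patient(scores, labels, xname = "scores")
  lab <- check_binary_labels(al$labels)
  s <- as.numeric(al$x)
  if (anyNA(s)) stopf("scores must not be missing")
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0 || n0 == 0)
    stopf("need at least one case and one control (got %d/%d)", n1, n0)
  r <- rank(s)  # midranks
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUC per column of a score matrix (same labels), used by the subset
# enumeration where tens of thousands of AUCs are needed
.auc_columns <- function(score_mat, lab) {
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  case <- lab == 1L
  vapply(seq_len(ncol(score_mat)), function(j) {
    r <- rank(score_mat[, j])
    (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
}

#' Empirical ROC curve
#'
#' Stepwise curve over all distinct score thresholds, from (0, 0) to
#' (1, 1); its trapezoidal area equals [empirical_auc()] (ties appear as
#' diagonal segments, i.e. the half-credit convention).
#'
#' @inheritParams empirical_auc
#' @param score_name label carried into the result.
#' @param sample_type optional stratum tag.
#' @return object of class `meth_roc`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_cases`, `n_controls`,
#'   `score_name`, `sample_type`.
#' @export
roc_curve <- function(scores, labels, score_name = "score",
                      sample_type = NA_character_) {
  al <- align_by_patient(scores, labels, xname = "scores")
  lab <- check_binary_labels(al$labels)
  s <- as.numeric(al$x)
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0 || n0 == 0)
    stopf("need at least one case and one control (got %d/%d)", n1, n0)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s >= t & lab == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(s >= t & lab == 0L) / n0, 0)
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  # trapezoid over consecutive points (curve necessarily ends at (1,1))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_cases = n1, n_controls = n0,
                 score_name = score_name, sample_type = sample_type),
            class = "meth_roc")
}

#' @export
print.meth_roc <- function(x, ...) {
  cat(sprintf("<meth_roc '%s'%s>: AUC = %.4f (%d cases / %d controls, %d points)\n",
              x$score_name,
              if (is.na(x$sample_type)) "" else paste0(", ", x$sample_type),
              x$auc, x$n_cases, x$n_controls, nrow(x$points)))
  invisible(x)
}

#' Marker-subset count score
#'
#' Number of positive (level > 0) markers within a subset of the panel.
#'
#' @param marker_levels named numeric vector of merged marker levels, or a
#'   matrix with markers as columns.
#' @param subset character vector of marker ids, non-empty.
#' @return integer count(s).
#' @export
subset_count_score <- function(marker_levels, subset) {
  if (!length(subset)) stopf("subset must be non-empty")
  nm <- if (is.null(dim(marker_levels))) names(marker_levels)
        else colnames(marker_levels)
  unknown <- setdiff(subset, nm)
  if (length(unknown))
    stopf("unknown marker(s): %s", paste(unknown, collapse = ", "))
  if (is.null(dim(marker_levels))) sum(marker_levels[subset] > 0)
  else as.integer(rowSums(marker_levels[, subset, drop = FALSE] > 0))
}

#' Enumerate AUCs of all k-marker subsets
#'
#' For every one of the `choose(p, k)` subsets of the panel's markers,
#' scores each sample by its subset marker count and computes the empirical
#' AUC against the biopsy labels. Enumeration is exhaustive and ordered
#' lexicographically by marker id, so results are deterministic.
#'
#' @param profiles data frame from [build_profiles()] (one sample type), or
#'   a marker-level matrix with markers as columns.
#' @param labels binary labels aligned with the profile rows.
#' @param k subset size (1 to 6 are practical; `choose(19, 6) = 27132`).
#' @param sample_type optional stratum tag.
#' @return object of class `auc_distribution`: list with `k`, `subsets`
#'   (character, markers joined by `+`), `aucs`, and `summary`
#'   (mean, sd, min, max).
#' @export
enumerate_subset_aucs <- function(profiles, labels, k,
                                  sample_type = NA_character_) {
  mmat <- if (is.matrix(profiles)) profiles else profile_marker_matrix(profiles)
  lab <- check_binary_labels(labels)
  if (length(lab) != nrow(mmat))
    stopf("labels length (%d) != number of samples (%d)", length(lab),
          nrow(mmat))
  markers <- sort(colnames(mmat))
  if (k < 1 || k > length(markers))
    stopf("k must lie in [1, %d]", length(markers))
  pos <- (mmat[, markers, drop = FALSE] > 0) + 0
  combs <- utils::combn(length(markers), k)
  ind <- matrix(0, nrow = length(markers), ncol = ncol(combs))
  ind[cbind(as.vector(combs),
            rep(seq_len(ncol(combs)), each = k))] <- 1
  scores <- pos %*% ind
  aucs <- .auc_columns(scores, lab)
  subsets <- apply(combs, 2, function(ix) paste(markers[ix], collapse = "+"))
  structure(list(
    k = k, sample_type = sample_type, subsets = subsets, aucs = aucs,
    summary = c(mean = mean(aucs), sd = stats::sd(aucs), min = min(aucs),
                max = max(aucs))
  ), class = "auc_distribution")
}

#' @export
print.auc_distribution <- function(x, ...) {
  cat(sprintf("<auc_distribution k=%d%s>: %d subsets, mean %.4f, sd %.4f, range [%.4f, %.4f]\n",
              x$k,
              if (is.na(x$sample_type)) "" else paste0(", ", x$sample_type),
              length(x$aucs), x$summary["mean"], x$summary["sd"],
              x$summary["min"], x$summary["max"]))
  invisible(x)
}

#' AUC of one named marker subset
#'
#' Count-score AUC for a single subset (the full panel reproduces the
#' n-of-19 AUC).
#'
#' @inheritParams enumerate_subset_aucs
#' @param subset character vector of marker ids.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_panel <- function(profiles, labels, subset) {
  mmat <- if (is.matrix(profiles)) profiles else profile_marker_matrix(profiles)
  empirical_auc(subset_count_score(mmat, subset), labels)
}
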