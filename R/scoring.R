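#' Merge dual-assay levels to marker levels
#'
#' Five CpG islands of the default panel carry two assays interrogating
#' different portions of the island. Their results are merged by taking the
#' highest methylation level detected: a marker is positive if either assay
#' is positive (union rule), and the larger level is taken to best reflect
#' the island's methylation status given that all fragments of an island are
#' not recovered from urine DNA in comparable copy number. Single-assay
#' markers pass through unchanged.
#'
#' @param assay_levels named numeric vector over the panel's assays, or a
#'   matrix with assays as columns (one row per sample).
#' @param panel a `meth_panel`.
#' @return named vector (or matrix) of merged levels over the panel markers,
#'   in panel marker order.
#' @examples
#' panel <- default_panel()
#' x <- setNames(numeric(24), panel$assays$assay_id)
#' x[c("KIFC2", "KIFC2rc")] <- c(3, 5)
#' merge_dual_assays(x, panel)[["KIFC2"]]  # 5
#' @export
merge_dual_assays <- function(assay_levels, panel = default_panel()) {
  vec <- is.null(dim(assay_levels))
  m <- if (vec) matrix(assay_levels, nrow = 1,
                       dimnames = list(NULL, names(assay_levels)))
       else as.matrix(assay_levels)
  if (is.null(colnames(m))) stopf("assay_levels must be named by assay id")
  missing <- setdiff(panel$assays$assay_id, colnames(m))
  if (length(missing))
    stopf("assay level(s) missing for: %s", paste(missing, collapse = ", "))
  unknown <- setdiff(colnames(m), panel$assays$assay_id)
  if (length(unknown))
    stopf("assay(s) not in panel: %s", paste(unknown, collapse = ", "))
  out <- vapply(panel$markers$marker_id, function(mk) {
    ids <- panel$assays$assay_id[panel$assays$marker_id == mk]
    if (length(ids) == 1) m[, ids]
    else do.call(pmax, lapply(ids, function(a) m[, a]))
  }, numeric(nrow(m)))
  if (nrow(m) == 1) out <- stats::setNames(as.numeric(out),
                                           panel$markers$marker_id)
  if (vec) out else {
    dimnames(out) <- list(rownames(m), panel$markers$marker_id)
    out
  }
}

.check_marker_vector <- function(marker_levels, n_markers) {
  if (length(marker_levels) != n_markers)
    stopf("expected %d marker levels, got %d", n_markers,
          length(marker_levels))
  if (anyNA(marker_levels) || any(marker_levels < 0))
    stopf("marker levels must be non-negative and non-missing")
  marker_levels
}

#' Count positive markers (the n-of-19 score)
#'
#' A marker is positive when its merged methylation level is strictly
#' greater than 0; the count over the panel is the sample's cumulative
#' methylation score.
#'
#' @param marker_levels numeric vector of merged marker levels.
#' @param n_markers expected panel size (default 19).
#' @return integer count in `[0, n_markers]`.
#' @export
count_positive_markers <- function(marker_levels, n_markers = 19) {
  sum(.check_marker_vector(marker_levels, n_markers) > 0)
}

#' Average methylation over the panel
#'
#' Sum of the merged marker levels divided by the panel size. Dual-assay
#' islands contribute their merged (maximum) level once, so that no island
#' is double-weighted.
#'
#' @inheritParams count_positive_markers
#' @return mean level (unitless).
#' @export
average_methylation <- function(marker_levels, n_markers = 19) {
  sum(.check_marker_vector(marker_levels, n_markers)) / n_markers
}

#' Classify a sample from its marker count
#'
#' Test-positive when at least `threshold` markers are methylated; the
#' default threshold of 6-of-19 is the operating point chosen for a target
#' specificity of 70%.
#'
#' @param n_positive integer vector of positive-marker counts.
#' @param threshold decision threshold (inclusive), >= 1.
#' @return logical vector, `TRUE` = test-positive.
#' @examples
#' classify_sample(c(5, 6, 12))  # FALSE TRUE TRUE
#' @export
classify_sample <- function(n_positive, threshold = 6) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1)
    stopf("threshold must be a single number >= 1")
  n_positive >= threshold
}

#' Build per-sample methylation profiles
#'
#' Turns long-format assay levels into one profile per patient and sample
#' type: the 24 raw assay levels, the 19 merged marker levels, and the two
#' sample scores (`n_positive`, `avg_methylation`).
#'
#' @param assay_levels long data frame from [read_cq_table()] (columns
#'   `patient_id`, `sample_type`, `assay_id`, `level`).
#' @param panel a `meth_panel`.
#' @return data frame with columns `patient_id`, `sample_type`, one column
#'   per marker (merged levels), `n_positive` and `avg_methylation`; the raw
#'   assay-level wide matrix is attached as `attr(, "assay_levels")` and the
#'   marker ids as `attr(, "markers")`.
#' @export
build_profiles <- function(assay_levels, panel = default_panel()) {
  needed <- c("patient_id", "sample_type", "assay_id", "level")
  miss <- setdiff(needed, names(assay_levels))
  if (length(miss))
    stopf("assay_levels missing column(s): %s", paste(miss, collapse = ", "))
  wide <- stats::reshape(
    assay_levels[, needed], direction = "wide",
    idvar = c("patient_id", "sample_type"), timevar = "assay_id"
  )
  names(wide) <- sub("^level\\.", "", names(wide))
  amat <- as.matrix(wide[, panel$assays$assay_id, drop = FALSE])
  if (anyNA(amat))
    stopf("incomplete assay set for some sample(s); run read_cq_table() %s",
          "with missing_action = 'impute' first")
  mmat <- merge_dual_assays(amat, panel)
  nm <- nrow(panel$markers)
  prof <- data.frame(patient_id = wide$patient_id,
                     sample_type = wide$sample_type,
                     stringsAsFactors = FALSE)
  prof <- cbind(prof, as.data.frame(mmat))
  prof$n_positive <- apply(mmat, 1, count_positive_markers, n_markers = nm)
  prof$avg_methylation <- apply(mmat, 1, average_methylation, n_markers = nm)
  ord <- order(prof$patient_id, prof$sample_type)
  prof <- prof[ord, , drop = FALSE]
  rownames(prof) <- NULL
  rownames(amat) <- NULL
  attr(prof, "assay_levels") <- amat[ord, , drop = FALSE]
  attr(prof, "markers") <- panel$markers$marker_id
  attr(prof, "assay_meta") <- wide[ord, c("patient_id", "sample_type")]
  prof
}

# marker-level matrix of a profiles data frame
profile_marker_matrix <- function(profiles) {
  markers <- attr(profiles, "markers")
  if (is.null(markers)) stopf("profiles lack marker metadata; use build_profiles()")
  as.matrix(profiles[, markers, drop = FALSE])
}

#' Write per-sample profiles as TSV
#'
#' @param profiles data frame from [build_profiles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
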