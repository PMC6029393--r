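#' Transform a quantification cycle into a methylation level
#'
#' MS-qPCR output is a Cq per well (lower Cq = more methylated template) or
#' no amplification. Levels are reported on an inverted scale so that larger
#' means more methylation: a reaction is positive when its Cq falls strictly
#' below the cutoff (default 32 cycles, the upper limit for a positive
#' reaction), and its level is `cutoff - cq`. No amplification, and any Cq at
#' or beyond the cutoff, map to level 0. With the default cutoff the working
#' range observed in urine DNA is 0 to 15 (Cq 17); levels above 15 are legal
#' and trigger a warning rather than clamping.
#'
#' A Cq exactly at the cutoff yields level 0 and is therefore negative under
#' the level > 0 positivity rule; calling it positive would create a
#' positive reaction carrying zero methylation signal, which every
#' downstream score treats as absence.
#'
#' @param cq numeric vector of Cq values in cycles; `NA` = no amplification.
#' @param cutoff positive cutoff in cycles (default 32).
#' @return numeric vector of levels, all >= 0.
#' @examples
#' cq_to_level(c(NA, 17, 31.2, 32, 33))  # 0 15 0.8 0 0
#' @export
cq_to_level <- function(cq, cutoff = 32) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff) ||
      cutoff <= 0)
    stopf("cutoff must be a single positive number")
  cq <- as.numeric(cq)
  bad <- !is.na(cq) & (!is.finite(cq) | cq <= 0)
  if (any(bad))
    stopf("invalid Cq value(s): %s (must be positive and finite, or NA)",
          paste(unique(cq[bad]), collapse = ", "))
  level <- ifelse(is.na(cq) | cq >= cutoff, 0, cutoff - cq)
  if (any(level > 15))
    warnf("%d level(s) above 15 (Cq below %g); kept unclamped",
          sum(level > 15), cutoff - 15)
  level
}

#' Aggregate replicate wells into one level
#'
#' MS-qPCR reactions are run in duplicate; one level per assay and sample is
#' needed downstream. The default rule takes the maximum level (equivalently
#' the minimum Cq), consistent with the highest-methylation-level convention
#' used to merge dual assays. `mean_of_positives` averages the positive
#' replicates only (0 if none); `mean` averages all replicates.
#'
#' @param levels numeric vector of replicate levels (all >= 0).
#' @param rule aggregation rule.
#' @return a single level.
#' @examples
#' aggregate_replicates(c(0, 4))             # 4
#' aggregate_replicates(c(3, 5), "mean")     # 4
#' @export
aggregate_replicates <- function(levels,
                                 rule = c("max", "mean_of_positives", "mean")) {
  rule <- match.arg(rule)
  if (!length(levels)) stopf("cannot aggregate an empty replicate set")
  if (anyNA(levels) || any(levels < 0))
    stopf("replicate levels must be non-negative and non-missing")
  switch(rule,
    max = max(levels),
    mean = mean(levels),
    mean_of_positives = if (any(levels > 0)) mean(levels[levels > 0]) else 0
  )
}

# sniff the field delimiter of a delimited text file
.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- c("\t" = lengths(regmatches(first, gregexpr("\t", first))),
              ","  = lengths(regmatches(first, gregexpr(",", first))),
              ";"  = lengths(regmatches(first, gregexpr(";", first))))
  if (all(counts == 0)) stopf("could not detect delimiter in %s", path)
  names(counts)[which.max(counts)]
}

#' Read a raw Cq table and produce per-assay methylation levels
#'
#' Input is a long delimited table (TSV/CSV; delimiter sniffed unless given)
#' with columns `patient_id`, `sample_type` (`DRE` or `FV`), `assay_id`,
#' `replicate`, `cq` (empty, `NA` or a no-amplification sentinel for no
#' amplification). Assay ids are matched against the panel including
#' declared aliases; control-assay rows are diverted to the QC report.
#' Replicates are aggregated with [aggregate_replicates()], Cq values
#' transformed with [cq_to_level()], and assays absent for a sample imputed
#' as level 0 (absence of amplification) with a warning — or the sample is
#' excluded when `missing_action = "exclude"`.
#'
#' @param path delimited file path.
#' @param panel a `meth_panel` (default [default_panel()]).
#' @param cutoff Cq positivity cutoff in cycles.
#' @param rule replicate aggregation rule, see [aggregate_replicates()].
#' @param missing_action `"impute"` (level 0) or `"exclude"` (drop sample).
#' @param sep,dec field delimiter and decimal mark; `sep = NULL` sniffs.
#' @return data frame of assay levels (`patient_id`, `sample_type`,
#'   `assay_id`, `level`), one row per patient x sample type x panel assay,
#'   with a per-sample QC report in `attr(, "qc")` (assays observed, assays
#'   imputed, control assay status).
#' @export
read_cq_table <- function(path, panel = default_panel(), cutoff = 32,
                          rule = "max",
                          missing_action = c("impute", "exclude"),
                          sep = NULL, dec = ".") {
  missing_action <- match.arg(missing_action)
  if (!file.exists(path)) stopf("Cq table not found: %s", path)
  sep <- sep %||% .sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  needed <- c("patient_id", "sample_type", "assay_id", "replicate", "cq")
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stopf("Cq table missing column(s): %s", paste(miss, collapse = ", "))
  raw$sample_type <- toupper(trimws(raw$sample_type))
  bad_st <- setdiff(unique(raw$sample_type), c("DRE", "FV"))
  if (length(bad_st))
    stopf("unknown sample_type value(s): %s", paste(bad_st, collapse = ", "))
  raw$cq[tolower(trimws(raw$cq)) %in%
           c("noamp", "no_amp", "no-amplification", "undetermined")] <- NA
  raw$cq <- as.numeric(raw$cq)
  raw$replicate <- as.integer(raw$replicate)
  if (anyNA(raw$replicate) || any(raw$replicate < 1))
    stopf("replicate must be a positive integer")

  amap <- assay_alias_map(panel)
  ctrl_ids <- panel$control_assays$assay_id
  is_ctrl <- raw$assay_id %in% ctrl_ids
  unknown <- setdiff(unique(raw$assay_id[!is_ctrl]), names(amap))
  if (length(unknown))
    stopf("unknown assay id(s): %s", paste(unknown, collapse = ", "))
  raw$assay_id[!is_ctrl] <- unname(amap[raw$assay_id[!is_ctrl]])

  key <- paste(raw$patient_id, raw$sample_type, raw$assay_id, raw$replicate,
               sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (patient, sample, assay, replicate) row(s): %s",
          paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))

  raw$level <- cq_to_level(raw$cq, cutoff = cutoff)

  ctrl <- raw[is_ctrl, , drop = FALSE]
  raw <- raw[!is_ctrl, , drop = FALSE]

  agg <- stats::aggregate(
    list(level = raw$level),
    by = list(patient_id = raw$patient_id, sample_type = raw$sample_type,
              assay_id = raw$assay_id),
    FUN = function(x) aggregate_replicates(x, rule = rule)
  )

  # complete every sample to the full assay set
  samples <- unique(agg[, c("patient_id", "sample_type")])
  full <- merge(samples, data.frame(assay_id = panel$assays$assay_id),
                by = NULL)
  out <- merge(full, agg, by = c("patient_id", "sample_type", "assay_id"),
               all.x = TRUE)
  imputed <- is.na(out$level)
  qc <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    sel <- out$patient_id == samples$patient_id[i] &
      out$sample_type == samples$sample_type[i]
    csel <- ctrl$patient_id == samples$patient_id[i] &
      ctrl$sample_type == samples$sample_type[i]
    data.frame(
      patient_id = samples$patient_id[i],
      sample_type = samples$sample_type[i],
      assays_observed = sum(sel & !imputed),
      assays_imputed = sum(sel & imputed),
      controls_detected = sum(ctrl$level[csel] > 0),
      controls_assayed = sum(csel),
      stringsAsFactors = FALSE
    )
  }))
  if (any(imputed)) {
    nsamp <- nrow(unique(out[imputed, c("patient_id", "sample_type")]))
    if (missing_action == "impute") {
      warnf("%d assay record(s) absent across %d sample(s); imputed as level 0",
            sum(imputed), nsamp)
      out$level[imputed] <- 0
    } else {
      warnf("excluding %d sample(s) with absent assay record(s)", nsamp)
      bad <- unique(out[imputed, c("patient_id", "sample_type")])
      keep <- !(paste(out$patient_id, out$sample_type) %in%
                  paste(bad$patient_id, bad$sample_type))
      out <- out[keep, , drop = FALSE]
    }
  }
  out <- out[order(out$patient_id, out$sample_type, out$assay_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- qc
  out
}

#' Write assay levels as canonical long-format TSV
#'
#' @param levels data frame from [read_cq_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assay_levels <- function(levels, path) {
  utils::write.table(levels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
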