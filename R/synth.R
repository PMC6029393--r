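#' Published per-assay positivity proportions (post-DRE urine)
#'
#' The observed per-assay positivity proportions in post-DRE urine that
#' calibrate the synthetic generator: for cases the fraction of the 38
#' biopsy-positive patients whose assay was methylated, for controls one
#' minus the fraction of the 49 biopsy-negative patients whose assay was
#' negative. Combined (merged dual-assay) marker proportions are included
#' under `marker_case` / `marker_control` for the five dual-assay markers.
#'
#' @return list with named numeric vectors `case` and `control` over the 24
#'   assays, `marker_case` / `marker_control` over the 19 markers, and the
#'   stratum sizes `n_cases` (38) and `n_controls` (49).
#' @export
default_params_from_table2 <- function() {
  case_num <- c(
    ADCY4 = 23, AOX1rc = 27, APC2 = 10, CXCL14 = 8, CXCL14rc = 6,
    EPHX3 = 25, KIFC2 = 25, KIFC2rc = 20, GFRA2 = 17, GSTP1 = 18,
    HEMK1 = 15, HOXA7 = 32, HOXB5 = 29, HOXB5rc = 27, HOXD3a = 19,
    HOXD3b = 29, HOXD9 = 26, HOXD10 = 23, MOXD1 = 16, NEUROG3 = 14,
    NODAL = 24, NODALrc = 20, RASSF5 = 9, RASSF5rc = 10
  )
  control_neg <- c(
    ADCY4 = 38, AOX1rc = 34, APC2 = 44, CXCL14 = 49, CXCL14rc = 49,
    EPHX3 = 35, KIFC2 = 38, KIFC2rc = 42, GFRA2 = 41, GSTP1 = 40,
    HEMK1 = 46, HOXA7 = 39, HOXB5 = 40, HOXB5rc = 35, HOXD3a = 45,
    HOXD3b = 37, HOXD9 = 29, HOXD10 = 42, MOXD1 = 41, NEUROG3 = 42,
    NODAL = 40, NODALrc = 41, RASSF5 = 46, RASSF5rc = 43
  )
  # merged dual-assay (combined) positives; singles equal their one assay
  comb_case <- c(CXCL14 = 9, KIFC2 = 30, HOXB5 = 32, NODAL = 30, RASSF5 = 17)
  comb_control_neg <- c(CXCL14 = 49, KIFC2 = 34, HOXB5 = 29, NODAL = 35,
                        RASSF5 = 40)
  panel <- default_panel()
  a2m <- stats::setNames(panel$assays$marker_id, panel$assays$assay_id)
  marker_case <- marker_control <- stats::setNames(
    numeric(nrow(panel$markers)), panel$markers$marker_id)
  for (mk in panel$markers$marker_id) {
    if (mk %in% names(comb_case)) {
      marker_case[mk] <- comb_case[[mk]] / 38
      marker_control[mk] <- 1 - comb_control_neg[[mk]] / 49
    } else {
      a <- names(a2m)[a2m == mk]
      marker_case[mk] <- case_num[[a]] / 38
      marker_control[mk] <- 1 - control_neg[[a]] / 49
    }
  }
  list(case = case_num / 38, control = 1 - control_neg / 49,
       marker_case = marker_case, marker_control = marker_control,
       n_cases = 38L, n_controls = 49L)
}

# Decompose assay-level positivity rates (u1, u2) and a combined rate (c)
# into a marker-state probability p_m and conditional detection
# probabilities d_i, assuming the two assays detect a methylated island
# independently: u_i = p_m * d_i, c = p_m * (1 - (1 - d1)(1 - d2)) =>
# p_m = u1 * u2 / (u1 + u2 - c). Capped at 1; some published combinations
# (near-disjoint assays) are infeasible under conditional independence, in
# which case the cap preserves the assay-level rates exactly while the
# combined rate deviates slightly.
.decompose_dual <- function(u1, u2, cc) {
  denom <- u1 + u2 - cc
  p_m <- if (denom <= 0 || u1 * u2 / denom > 1) 1 else u1 * u2 / denom
  p_m <- max(p_m, u1, u2, cc)  # detection probs must be <= 1
  p_m <- min(p_m, 1)
  c(p_m = p_m, d1 = if (p_m > 0) u1 / p_m else 0,
    d2 = if (p_m > 0) u2 / p_m else 0)
}

#' Default generator parameters
#'
#' Constructs the parameter set the synthetic cohort is drawn from. The
#' defaults encode the study conditions: 42 cases and 52 controls; per-assay
#' positivity probabilities calibrated to the published post-DRE
#' proportions (via [default_params_from_table2()]), with positivity
#' generated at marker level and split to assays through conditionally
#' independent detection; levels for positive reactions from a truncated
#' normal (mean 6, sd 3) on (0, 15], rounded to 0.1 (the instrument's Cq
#' resolution); PSA log-normal with medians 6.4 (cases) and 5.2 (controls);
#' sample availability matching the 60 paired / 27 DRE-only / 7 FV-only
#' split of the 94 patients; a 0.8 probability that a marker's state is
#' shared between a patient's DRE and FV samples; first-void attenuation of
#' assay detection for AOX1rc, GFRA2 and NEUROG3 (the three assays better
#' recovered after DRE); and a centered log-odds contrast of 0.8 between
#' elevated- and low-risk cases.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param seed integer seed; mandatory for reproducibility.
#' @param level_mean,level_sd truncated-normal parameters for positive
#'   levels.
#' @param dre_fv_agreement probability a marker state is shared between the
#'   two sample types of one patient.
#' @param fv_attenuation named multipliers (< 1 attenuates) on first-void
#'   detection probability for specific assays in cases.
#' @param capra_effect log-odds gap in case marker positivity between
#'   elevated-risk (CAPRA >= 3) and low-risk (CAPRA 1-2) cases, applied as
#'   a centered contrast so the marginal case rates stay at calibration.
#' @param p_group2 probability a case is elevated-risk (default 20/35, the
#'   published DRE group split).
#' @param missing_rate probability an assay record is absent from the
#'   emitted Cq table.
#' @param rep_agreement probability the duplicate well of a positive
#'   reaction also amplifies.
#' @param psa_meanlog,psa_sdlog log-normal PSA parameters, `c(case,
#'   control)`.
#' @param p_sample probabilities of the three availability patterns
#'   `c(both, dre_only, fv_only)`.
#' @return list of class `generator_params`.
#' @export
default_generator_params <- function(n_cases = 42, n_controls = 52,
                                     seed = 20180703,
                                     level_mean = 6, level_sd = 3,
                                     dre_fv_agreement = 0.8,
                                     fv_attenuation = c(AOX1rc = 0.6,
                                                        GFRA2 = 0.9,
                                                        NEUROG3 = 0.6),
                                     capra_effect = 0.8,
                                     p_group2 = 20 / 35,
                                     missing_rate = 0,
                                     rep_agreement = 0.9,
                                     psa_meanlog = c(log(6.4), log(5.2)),
                                     psa_sdlog = c(0.46, 0.39),
                                     p_sample = c(60, 27, 7) / 94) {
  tab <- default_params_from_table2()
  panel <- default_panel()
  dual <- panel$markers$marker_id[panel$markers$n_assays == 2]
  decomp <- function(rates, marker_rates) {
    out <- list()
    for (mk in panel$markers$marker_id) {
      ids <- panel$assays$assay_id[panel$assays$marker_id == mk]
      if (length(ids) == 1) {
        out[[mk]] <- list(p_m = unname(rates[ids]), d = stats::setNames(1, ids))
      } else {
        dd <- .decompose_dual(rates[[ids[1]]], rates[[ids[2]]],
                              marker_rates[[mk]])
        out[[mk]] <- list(p_m = unname(dd[["p_m"]]),
                          d = stats::setNames(c(dd[["d1"]], dd[["d2"]]), ids))
      }
    }
    out
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls, seed = seed,
    panel = panel,
    p_pos_case = tab$case, p_pos_control = tab$control,
    marker_case = decomp(tab$case, tab$marker_case),
    marker_control = decomp(tab$control, tab$marker_control),
    level_mean = level_mean, level_sd = level_sd,
    dre_fv_agreement = dre_fv_agreement,
    fv_attenuation = fv_attenuation,
    capra_effect = capra_effect, p_group2 = p_group2,
    missing_rate = missing_rate, rep_agreement = rep_agreement,
    psa_meanlog = psa_meanlog, psa_sdlog = psa_sdlog,
    p_sample = p_sample
  ), class = "generator_params")
}

.check_prob <- function(p, what) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stopf("%s must be probabilities in [0, 1]", what)
  p
}

# truncated normal on (0, 15], rounded to the 0.1 Cq resolution
.draw_levels <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  lo <- stats::pnorm(0, mean, sd); hi <- stats::pnorm(15, mean, sd)
  x <- stats::qnorm(stats::runif(n, lo, hi), mean, sd)
  pmax(round(x, 1), 0.1)
}

#' Generate a synthetic urine-methylation cohort
#'
#' Draws a cohort under the generator's statistical model: per-patient
#' marker methylation states (Bernoulli per marker, probabilities per
#' biopsy stratum, elevated-risk cases shifted on the log-odds scale),
#' assay-level detection conditional on the marker state, semi-quantitative
#' levels for detected assays back-transformed to Cq (`32 - level`) so that
#' the emitted table exercises the real ingest path, duplicate wells, and a
#' clinical table (biopsy outcome, age, PSA, Gleason, positive cores, risk
#' group). Deterministic given `params$seed`.
#'
#' @param params a `generator_params` from [default_generator_params()].
#' @return list of class `synthetic_cohort`: `cq` (long Cq table),
#'   `clinical`, `truth` (per-patient marker states per sample type and the
#'   params).
#' @export
generate_cohort <- function(params = default_generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  .check_prob(params$p_pos_case, "p_pos_case")
  .check_prob(params$p_pos_control, "p_pos_control")
  .check_prob(c(params$dre_fv_agreement, params$missing_rate,
                params$rep_agreement, params$p_group2, params$p_sample),
              "rate parameters")
  if (is.null(params$seed)) stopf("params$seed is mandatory")
  with_seed(params$seed, .generate_cohort_impl(params))
}

.generate_cohort_impl <- function(params) {
  panel <- params$panel
  markers <- panel$markers$marker_id
  nM <- length(markers)
  n <- params$n_cases + params$n_controls
  pid <- sprintf("P%03d", seq_len(n))
  biopsy <- c(rep(1L, params$n_cases), rep(0L, params$n_controls))
  grp2 <- biopsy == 1L & stats::runif(n) < params$p_group2
  capra_group <- ifelse(biopsy == 0L, 0L, ifelse(grp2, 2L, 1L))
  # centered log-odds contrast: marginal case rate stays at calibration
  w2 <- params$p_group2
  shift <- ifelse(capra_group == 2L, params$capra_effect * (1 - w2),
                  ifelse(capra_group == 1L, -params$capra_effect * w2, 0))

  avail <- sample(c("both", "dre_only", "fv_only"), n, replace = TRUE,
                  prob = params$p_sample)
  has_dre <- avail != "fv_only"
  has_fv <- avail != "dre_only"

  p_marker <- matrix(NA_real_, n, nM, dimnames = list(pid, markers))
  for (j in seq_len(nM)) {
    mk <- markers[j]
    pc <- params$marker_case[[mk]]$p_m
    p0 <- params$marker_control[[mk]]$p_m
    base <- ifelse(biopsy == 1L, pc, p0)
    lo <- stats::qlogis(pmin(pmax(base, 1e-9), 1 - 1e-9))
    p <- stats::plogis(lo + ifelse(biopsy == 1L, shift, 0))
    p[base == 0] <- 0; p[base == 1] <- 1
    p_marker[, j] <- p
  }
  state_dre <- matrix(stats::runif(n * nM) < p_marker, n, nM,
                      dimnames = list(pid, markers))
  redraw <- matrix(stats::runif(n * nM) < p_marker, n, nM)
  keep <- matrix(stats::runif(n * nM) < params$dre_fv_agreement, n, nM)
  state_fv <- ifelse(keep, state_dre, redraw)
  dimnames(state_fv) <- dimnames(state_dre)

  cq_rows <- list()
  emit <- function(pids, st, assay, cqv) {
    # duplicate wells: replicate 1 carries the reaction, replicate 2
    # re-amplifies with probability rep_agreement
    nn <- length(pids)
    if (!nn) return()
    rep2 <- ifelse(!is.na(cqv) & stats::runif(nn) < params$rep_agreement,
                   cqv, NA_real_)
    cq_rows[[length(cq_rows) + 1L]] <<- data.frame(
      patient_id = rep(pids, 2), sample_type = st,
      assay_id = assay, replicate = rep(c(1L, 2L), each = nn),
      cq = c(cqv, rep2), stringsAsFactors = FALSE)
  }
  for (st in c("DRE", "FV")) {
    present <- if (st == "DRE") has_dre else has_fv
    state <- if (st == "DRE") state_dre else state_fv
    for (mk in markers) {
      info_c <- params$marker_case[[mk]]; info_0 <- params$marker_control[[mk]]
      for (a in names(info_c$d)) {
        d <- ifelse(biopsy == 1L, info_c$d[[a]], info_0$d[[a]])
        if (st == "FV" && a %in% names(params$fv_attenuation))
          d <- ifelse(biopsy == 1L, d * params$fv_attenuation[[a]], d)
        detected <- present & state[, mk] & (stats::runif(n) < d)
        lev <- numeric(n)
        lev[detected] <- .draw_levels(sum(detected), params$level_mean,
                                      params$level_sd)
        cqv <- ifelse(detected, 32 - lev, NA_real_)
        keep_row <- present & (stats::runif(n) >= params$missing_rate)
        emit(pid[keep_row], st, a, cqv[keep_row])
      }
    }
    # recovery controls amplify in every sample (QC metadata)
    for (i in seq_len(nrow(panel$control_assays)))
      emit(pid[present], st, panel$control_assays$assay_id[i],
           32 - .draw_levels(sum(present), 10, 2))
  }
  cq <- do.call(rbind, cq_rows)
  cq <- cq[order(cq$patient_id, cq$sample_type, cq$assay_id, cq$replicate), ]
  rownames(cq) <- NULL

  age <- round(stats::rnorm(n, ifelse(biopsy == 1L, 67.1, 63.9),
                            ifelse(biopsy == 1L, 7.1, 7.6)))
  psa <- round(stats::rlnorm(n,
                             ifelse(biopsy == 1L, params$psa_meanlog[1],
                                    params$psa_meanlog[2]),
                             ifelse(biopsy == 1L, params$psa_sdlog[1],
                                    params$psa_sdlog[2])), 2)
  gleason <- ifelse(biopsy == 1L,
                    sample(c(6L, 7L, 8L, 9L, 10L), n, replace = TRUE,
                           prob = c(0.45, 0.19, 0.16, 0.10, 0.10)), NA)
  cores <- ifelse(biopsy == 1L, pmin(12L, 1L + stats::rpois(n, 3)), NA)
  clinical <- data.frame(
    patient_id = pid, biopsy = biopsy, age = age, psa = psa,
    gleason = gleason, positive_cores = cores, capra_group = capra_group,
    has_dre = has_dre, has_fv = has_fv, stringsAsFactors = FALSE)

  structure(list(cq = cq, clinical = clinical,
                 truth = list(params = params, state_dre = state_dre,
                              state_fv = state_fv)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort>: %d patients (%d cases / %d controls), %d Cq rows\n",
    nrow(x$clinical), sum(x$clinical$biopsy == 1),
    sum(x$clinical$biopsy == 0), nrow(x$cq)))
  invisible(x)
}

#' Write a synthetic cohort as ingest-ready fixtures
#'
#' Writes `cq_table.tsv` and `clinical.tsv` in the dialect [read_cq_table()]
#' consumes; a generate-write-read round trip is lossless.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named character paths, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cq_path <- file.path(dir, "cq_table.tsv")
  cl_path <- file.path(dir, "clinical.tsv")
  utils::write.table(cohort$cq, cq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$clinical, cl_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(cq = cq_path, clinical = cl_path))
}

#' Read a clinical table
#'
#' @param path delimited file with at least `patient_id` and `biopsy`
#'   columns; `capra_group` and `psa` are used when present.
#' @param sep field delimiter (sniffed when `NULL`).
#' @return data frame.
#' @export
read_clinical_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("clinical table not found: %s", path)
  sep <- sep %||% .sniff_sep(path)
  cl <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("patient_id", "biopsy"), names(cl))
  if (length(miss))
    stopf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  cl$patient_id <- as.character(cl$patient_id)
  check_binary_labels(cl$biopsy)
  cl
}
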