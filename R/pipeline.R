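#' Run the full panel analysis pipeline
#'
#' End-to-end orchestration: ingest a raw Cq table (or generate a synthetic
#' cohort), build per-sample profiles, and emit every report the analysis
#' defines — the per-assay performance table, the threshold sweep, ROC
#' curves and AUCs for the marker count, average methylation and PSA,
#' subset-AUC distributions, paired DRE-vs-FV comparisons, risk-group
#' summaries, a QC report and a run manifest. The two sample-type strata
#' are analyzed independently; paired analyses run on the patients with
#' both.
#'
#' @param cq_path,clinical_path input tables ([read_cq_table()],
#'   [read_clinical_table()]); omit both to run on a synthetic cohort.
#' @param synth_params a `generator_params` used when no input paths are
#'   given (default [default_generator_params()] with `seed`).
#' @param panel a `meth_panel` or path to a panel config.
#' @param out_dir output directory; `NULL` computes without writing.
#' @param threshold decision threshold for the marker-count classifier.
#' @param thresholds sweep range.
#' @param subset_sizes subset sizes for AUC enumeration (default 2:6).
#' @param ci_method confidence-interval method, see [proportion_ci()].
#' @param seed seed forwarded to the synthetic generator and any seeded CI
#'   method.
#' @param verbose print per-stage accounting.
#' @return list of class `methpanel_run` with elements `profiles`, `qc`,
#'   `assay_table`, `sweep`, `roc` (list of `meth_roc`), `subset_aucs`,
#'   `paired` (differences table, test comparison, concordance),
#'   `group_summary`, `clinical`, `manifest`.
#' @export
run_pipeline <- function(cq_path = NULL, clinical_path = NULL,
                         synth_params = NULL, panel = NULL, out_dir = NULL,
                         threshold = 6, thresholds = 1:19,
                         subset_sizes = 2:6, ci_method = "wilson",
                         seed = 20180703, verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  panel <- if (is.null(panel) || is.character(panel)) load_panel(panel)
           else panel
  if (threshold < 1 || threshold > nrow(panel$markers))
    stopf("threshold must lie in [1, %d]", nrow(panel$markers))

  if (is.null(cq_path)) {
    params <- synth_params %||% default_generator_params(seed = seed)
    cohort <- generate_cohort(params)
    tmp <- file.path(tempdir(), sprintf("methpanel-synth-%d", params$seed))
    paths <- write_fixture(cohort, tmp)
    cq_path <- paths[["cq"]]; clinical_path <- paths[["clinical"]]
    say("synth: generated %d patients (seed %d)", nrow(cohort$clinical),
        params$seed)
  } else if (is.null(clinical_path)) {
    stopf("ingest: clinical_path is required when cq_path is given")
  }
  if (!file.exists(cq_path)) stopf("ingest: Cq table not found: %s", cq_path)
  if (!file.exists(clinical_path))
    stopf("ingest: clinical table not found: %s", clinical_path)

  levels <- suppressWarnings(read_cq_table(cq_path, panel = panel))
  clinical <- read_clinical_table(clinical_path)
  qc <- attr(levels, "qc")
  say("ingest: %d assay-level records, %d samples", nrow(levels), nrow(qc))

  profiles <- build_profiles(levels, panel = panel)
  n_dre <- sum(profiles$sample_type == "DRE")
  n_fv <- sum(profiles$sample_type == "FV")
  say("score: %d profiles (%d DRE, %d FV)", nrow(profiles), n_dre, n_fv)

  assay_table <- assay_performance_table(profiles, clinical, panel,
                                         method = ci_method, seed = seed)
  sweep <- threshold_sweep(profiles, clinical, thresholds = thresholds,
                           method = ci_method, seed = seed)
  say("diagnostics: %d assay rows, %d sweep rows", nrow(assay_table),
      nrow(sweep))

  roc <- list(); subset_aucs <- list()
  for (st in sort(unique(profiles$sample_type))) {
    sel <- profiles$sample_type == st
    labels <- .labels_for(profiles, clinical, st)
    roc[[paste0("n_positive_", st)]] <-
      roc_curve(profiles$n_positive[sel], unname(labels),
                score_name = "n_positive", sample_type = st)
    roc[[paste0("avg_methylation_", st)]] <-
      roc_curve(profiles$avg_methylation[sel], unname(labels),
                score_name = "avg_methylation", sample_type = st)
    idx <- match(profiles$patient_id[sel], clinical$patient_id)
    psa <- clinical$psa[idx]
    if (!is.null(psa) && sum(!is.na(psa)) > 0 &&
        length(unique(labels[!is.na(psa)])) == 2) {
      say("roc: %s PSA curve drops %d patient(s) with missing PSA", st,
          sum(is.na(psa)))
      roc[[paste0("psa_", st)]] <-
        roc_curve(psa[!is.na(psa)], unname(labels)[!is.na(psa)],
                  score_name = "psa", sample_type = st)
    }
    mmat <- profile_marker_matrix(profiles)[sel, , drop = FALSE]
    for (k in subset_sizes)
      subset_aucs[[sprintf("k%d_%s", k, st)]] <-
        enumerate_subset_aucs(mmat, unname(labels), k, sample_type = st)
  }

  # paired analyses on the intersection of the two strata
  paired <- NULL
  common <- intersect(profiles$patient_id[profiles$sample_type == "DRE"],
                      profiles$patient_id[profiles$sample_type == "FV"])
  if (length(common) >= 2) {
    sub <- profiles[profiles$patient_id %in% common, , drop = FALSE]
    for (a in c("assay_levels", "markers"))
      attr(sub, a) <- attr(profiles, a)
    attr(sub, "assay_levels") <-
      attr(profiles, "assay_levels")[profiles$patient_id %in% common, ,
                                     drop = FALSE]
    diffs <- paired_difference_table(sub)
    dre <- sub[sub$sample_type == "DRE", ]
    fv <- sub[sub$sample_type == "FV", ]
    dre <- dre[match(common, dre$patient_id), ]
    fv <- fv[match(common, fv$patient_id), ]
    labs <- stats::setNames(
      clinical$biopsy[match(common, clinical$patient_id)], common)
    calls_dre <- stats::setNames(classify_sample(dre$n_positive, threshold),
                                 common)
    calls_fv <- stats::setNames(classify_sample(fv$n_positive, threshold),
                                common)
    cmp <- compare_paired_tests(calls_dre, calls_fv, labs)
    conc <- concordance(calls_dre, calls_fv, labs)
    paired <- list(differences = diffs, comparison = cmp, concordance = conc,
                   n_pairs = length(common))
    say("compare: %d paired patients", length(common))
  }

  group_summary <- if (!is.null(clinical$capra_group))
    group_summaries(profiles, clinical) else NULL

  manifest <- list(
    package = "methpanel",
    version = as.character(utils::packageVersion("methpanel")),
    seed = seed, threshold = threshold, ci_method = ci_method,
    thresholds = thresholds, subset_sizes = subset_sizes,
    panel = panel$name,
    n_patients = length(unique(profiles$patient_id)),
    n_dre = n_dre, n_fv = n_fv,
    n_paired = if (is.null(paired)) 0L else paired$n_pairs,
    inputs = c(cq = cq_path, clinical = clinical_path)
  )

  run <- structure(list(
    profiles = profiles, qc = qc, assay_table = assay_table, sweep = sweep,
    roc = roc, subset_aucs = subset_aucs, paired = paired,
    group_summary = group_summary, clinical = clinical, manifest = manifest
  ), class = "methpanel_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write a pipeline run to disk
#'
#' Emits the machine-readable bundle: `profiles.tsv`, `qc.tsv`,
#' `table2.tsv` / `table4.tsv` (rounded report shapes) with full-precision
#' JSON twins, `table5.tsv`, ROC point TSVs, per-k subset-AUC TSVs and a
#' summary JSON, the paired-comparison JSON, `group_summary.tsv` and
#' `manifest.json`. Output is byte-identical across runs with an identical
#' configuration.
#'
#' @param run a `methpanel_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "methpanel_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  js <- function(x, name) jsonlite::write_json(
    x, file.path(out_dir, name), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  write_profiles(run$profiles, file.path(out_dir, "profiles.tsv"))
  tsv(run$qc, "qc.tsv")
  tsv(format_diagnostics(run$assay_table), "table2.tsv")
  tsv(format_diagnostics(run$sweep), "table4.tsv")
  js(run$assay_table, "assay_table_full.json")
  js(run$sweep, "threshold_sweep_full.json")
  for (nm in names(run$roc))
    tsv(run$roc[[nm]]$points, sprintf("roc_%s.tsv", nm))
  js(lapply(run$roc, function(r)
    list(score = r$score_name, sample_type = r$sample_type, auc = r$auc,
         n_cases = r$n_cases, n_controls = r$n_controls)),
    "roc_summary.json")
  if (length(run$subset_aucs)) {
    for (nm in names(run$subset_aucs)) {
      d <- run$subset_aucs[[nm]]
      tsv(data.frame(subset = d$subsets, auc = d$aucs),
          sprintf("subset_aucs_%s.tsv", nm))
    }
    js(lapply(run$subset_aucs, function(d)
      c(list(k = d$k, sample_type = d$sample_type,
             n_subsets = length(d$aucs)), as.list(d$summary))),
      "subset_auc_summary.json")
  }
  if (!is.null(run$paired)) {
    tsv(run$paired$differences, "table5.tsv")
    cmp <- run$paired$comparison
    js(list(n_pairs = run$paired$n_pairs,
            diff_sensitivity = cmp$diff_sensitivity,
            sens_ci = cmp$sens_ci, p_sens = cmp$p_sens,
            diff_specificity = cmp$diff_specificity,
            spec_ci = cmp$spec_ci, p_spec = cmp$p_spec,
            concordance = as.list(run$paired$concordance)),
       "paired_comparison.json")
  }
  if (!is.null(run$group_summary)) tsv(run$group_summary, "group_summary.tsv")
  js(run$manifest, "manifest.json")
  invisible(out_dir)
}

#' @export
print.methpanel_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<methpanel_run>: %d patients (%d DRE / %d FV, %d paired), panel '%s'\n",
              m$n_patients, m$n_dre, m$n_fv, m$n_paired, m$panel))
  for (nm in names(x$roc))
    cat(sprintf("  AUC %-22s %.4f\n", nm, x$roc[[nm]]$auc))
  invisible(x)
}
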