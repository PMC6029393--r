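# independent oracles and small fixture builders used across tests

# AUC by exhaustive case-control pair counting (half credit for ties)
brute_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  total <- 0
  for (a in cs) for (b in ct)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cs) * length(ct))
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
enum_wilcox_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(n, n1)
  u_all <- apply(picks, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs); hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# exact two-sided discordant-pair binomial p by direct enumeration
enum_mcnemar_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  probs <- stats::dbinom(0:n, n, 0.5)
  k <- min(b, c)
  min(1, 2 * sum(probs[seq_len(k + 1)]))
}

# Wilson interval as the roots of the score quadratic
# (1 + z^2/n) p^2 - (2 phat + z^2/n) p + phat^2 = 0
wilson_by_roots <- function(k, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  phat <- k / n
  roots <- Re(polyroot(c(phat^2, -(2 * phat + z^2 / n), 1 + z^2 / n)))
  sort(roots)
}

# profiles built from a marker-level matrix (both assays of a dual marker
# set to the marker level, so merged levels equal the input)
profiles_from_markers <- function(mmat, sample_type = "DRE") {
  panel <- methpanel::default_panel()
  stopifnot(identical(sort(colnames(mmat)), sort(panel$markers$marker_id)))
  pid <- sprintf("S%03d", seq_len(nrow(mmat)))
  grid <- expand.grid(i = seq_len(nrow(mmat)),
                      j = seq_len(nrow(panel$assays)))
  long <- data.frame(
    patient_id = pid[grid$i],
    sample_type = sample_type,
    assay_id = panel$assays$assay_id[grid$j],
    level = mmat[cbind(grid$i,
                       match(panel$assays$marker_id[grid$j],
                             colnames(mmat)))],
    stringsAsFactors = FALSE
  )
  methpanel::build_profiles(long, panel)
}

rand_marker_matrix <- function(n, p_pos = 0.4) {
  panel <- methpanel::default_panel()
  m <- matrix(ifelse(stats::runif(n * 19) < p_pos,
                     round(stats::runif(n * 19, 0.1, 15), 1), 0),
              nrow = n, dimnames = list(NULL, panel$markers$marker_id))
  m
}

# generator params with deterministic all-or-nothing methylation
perfect_params <- function(seed = 1, n_cases = 15, n_controls = 15) {
  p <- methpanel::default_generator_params(
    n_cases = n_cases, n_controls = n_controls, seed = seed,
    missing_rate = 0, rep_agreement = 1, capra_effect = 0,
    fv_attenuation = c(AOX1rc = 1, GFRA2 = 1, NEUROG3 = 1))
  for (mk in names(p$marker_case)) {
    p$marker_case[[mk]]$p_m <- 1
    p$marker_case[[mk]]$d[] <- 1
    p$marker_control[[mk]]$p_m <- 0
    p$marker_control[[mk]]$d[] <- 0
  }
  p$p_pos_case[] <- 1
  p$p_pos_control[] <- 0
  p
}

# small synthetic run shared by several test files (generated once)
shared_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- methpanel::generate_cohort(
      methpanel::default_generator_params(seed = 42))
    co
  }
})

cohort_profiles <- function(co) {
  dir <- file.path(tempdir(), paste0("methpanel-fix-", substr(digest_str(co), 1, 8)))
  paths <- methpanel::write_fixture(co, dir)
  lv <- suppressWarnings(methpanel::read_cq_table(paths[["cq"]]))
  methpanel::build_profiles(lv)
}

# tiny stand-in for a digest; enough to separate temp dirs per cohort
digest_str <- function(x) paste0(nrow(x$cq), "x", sum(x$clinical$biopsy))
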