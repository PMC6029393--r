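test_that("Cq transform maps cycles to the inverted level scale", {
  expect_equal(cq_to_level(NA), 0)            # no amplification
  expect_equal(cq_to_level(17), 15)           # strongest observed signal
  expect_equal(cq_to_level(33), 0)            # beyond cutoff
  expect_equal(cq_to_level(32), 0)            # at cutoff: negative reaction
  expect_equal(cq_to_level(31.2), 0.8)
  expect_equal(cq_to_level(c(NA, 17, 33)), c(0, 15, 0))
  expect_equal(cq_to_level(25, cutoff = 30), 5)
})

test_that("Cq transform rejects invalid input and warns above 15", {
  expect_error(cq_to_level(-3), "invalid Cq")
  expect_error(cq_to_level(0), "invalid Cq")
  expect_error(cq_to_level(Inf), "invalid Cq")
  expect_error(cq_to_level(20, cutoff = 0), "cutoff")
  expect_warning(lv <- cq_to_level(16), "above 15")
  expect_equal(lv, 16)  # logged, not clamped
})

test_that("Cq transform is strictly decreasing below cutoff, zero beyond", {
  cq <- seq(0.5, 31.5, by = 0.5)
  expect_warning(lv <- cq_to_level(cq), "above 15")
  expect_true(all(diff(lv) < 0))
  expect_true(all(cq_to_level(seq(32, 45)) == 0))
  expect_true(all(lv >= 0))
})

test_that("replicate aggregation follows the chosen rule", {
  expect_equal(aggregate_replicates(c(0, 4)), 4)
  expect_equal(aggregate_replicates(c(0, 0)), 0)
  expect_equal(aggregate_replicates(c(0, 0), "mean"), 0)
  expect_equal(aggregate_replicates(c(0, 0), "mean_of_positives"), 0)
  expect_equal(aggregate_replicates(c(3, 5), "mean"), 4)
  expect_equal(aggregate_replicates(c(0, 3, 5), "mean_of_positives"), 4)
  expect_error(aggregate_replicates(numeric(0)), "empty")
  expect_error(aggregate_replicates(c(-1, 2)), "non-negative")
})

test_that("max aggregation is idempotent and permutation-invariant", {
  set.seed(11)
  for (i in 1:25) {
    x <- round(runif(sample(1:6, 1), 0, 15), 1)
    m <- aggregate_replicates(x)
    expect_equal(aggregate_replicates(x[sample(seq_along(x))]), m)
    expect_equal(aggregate_replicates(c(x, m)), m)
  }
})

# in-code fixture: a complete 2-patient x 2-sample-type Cq table in duplicate
make_cq_fixture <- function(panel = default_panel()) {
  grid <- expand.grid(patient_id = c("P1", "P2"),
                      sample_type = c("DRE", "FV"),
                      assay_id = panel$assays$assay_id,
                      replicate = 1:2, stringsAsFactors = FALSE)
  set.seed(7)
  grid$cq <- ifelse(runif(nrow(grid)) < 0.5, NA,
                    round(runif(nrow(grid), 20, 31.9), 1))
  grid
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("a complete duplicate table aggregates to 48 records per patient", {
  tab <- make_cq_fixture()
  expect_equal(nrow(tab), 2 * 2 * 24 * 2)  # 96 wells per patient
  path <- write_tsv(tab, withr::local_tempfile(fileext = ".tsv"))
  lv <- read_cq_table(path)
  expect_equal(nrow(lv), 2 * 2 * 24)
  expect_equal(sum(lv$patient_id == "P1"), 48)
  expect_true(all(lv$level >= 0))
  qc <- attr(lv, "qc")
  expect_equal(nrow(qc), 4)
  expect_true(all(qc$assays_observed == 24))
  expect_true(all(qc$assays_imputed == 0))
})

test_that("replicate disagreement resolves to the positive well under max", {
  tab <- data.frame(patient_id = "P1", sample_type = "DRE",
                    assay_id = rep(default_panel()$assays$assay_id, each = 2),
                    replicate = rep(1:2, 24), cq = NA_real_)
  tab$cq[tab$assay_id == "ADCY4"] <- c(31.2, NA)
  path <- write_tsv(tab, withr::local_tempfile(fileext = ".tsv"))
  lv <- read_cq_table(path)
  expect_equal(lv$level[lv$assay_id == "ADCY4"], 0.8)
  expect_true(all(lv$level[lv$assay_id != "ADCY4"] == 0))
})

test_that("unknown ids, bad sample types and duplicate wells are rejected", {
  tab <- make_cq_fixture()
  bad <- tab
  bad$assay_id[1] <- "FOO"
  path <- write_tsv(bad, withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_cq_table(path), "FOO")

  bad <- tab
  bad$sample_type[3] <- "URINE"
  path <- write_tsv(bad, withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_cq_table(path), "URINE")

  bad <- rbind(tab, tab[5, ])
  path <- write_tsv(bad, withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_cq_table(path), "duplicate")
})

test_that("assay aliases are accepted and mapped to canonical ids", {
  tab <- make_cq_fixture()
  tab$assay_id[tab$assay_id == "HEMK1"] <- "HEMK1rc"
  tab$assay_id[tab$assay_id == "APC2"] <- "APC"
  path <- write_tsv(tab, withr::local_tempfile(fileext = ".tsv"))
  lv <- read_cq_table(path)
  expect_true(all(c("HEMK1", "APC2") %in% lv$assay_id))
  expect_false(any(c("HEMK1rc", "APC") %in% lv$assay_id))
})

test_that("missing assays are imputed as level 0 or the sample excluded", {
  tab <- make_cq_fixture()
  tab <- tab[!(tab$patient_id == "P1" & tab$sample_type == "DRE" &
                 tab$assay_id == "GSTP1"), ]
  path <- write_tsv(tab, withr::local_tempfile(fileext = ".tsv"))
  expect_warning(lv <- read_cq_table(path), "imputed")
  expect_equal(nrow(lv), 96)
  expect_equal(lv$level[lv$patient_id == "P1" & lv$sample_type == "DRE" &
                          lv$assay_id == "GSTP1"], 0)
  expect_equal(attr(lv, "qc")$assays_imputed[
    attr(lv, "qc")$patient_id == "P1" &
      attr(lv, "qc")$sample_type == "DRE"], 1)
  expect_warning(lv2 <- read_cq_table(path, missing_action = "exclude"),
                 "excluding")
  expect_equal(nrow(lv2), 72)
})

test_that("control assays feed QC, never the level table; CSV is sniffed", {
  tab <- make_cq_fixture()
  ctrl <- data.frame(patient_id = "P1", sample_type = "DRE",
                     assay_id = "NSD1", replicate = 1:2, cq = c(22, 23))
  tab <- rbind(tab, ctrl)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  lv <- read_cq_table(path)
  expect_false("NSD1" %in% lv$assay_id)
  qc <- attr(lv, "qc")
  expect_equal(qc$controls_detected[qc$patient_id == "P1" &
                                      qc$sample_type == "DRE"], 2)
})
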