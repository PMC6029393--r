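#' Marker panel definitions for methylation-specific qPCR
#'
#' A panel groups MS-qPCR assays under their parent CpG-island markers.
#' The default panel is the 19-CpG-island / 24-assay prostate-cancer panel:
#' 19 islands associated with 18 genes, five of which (CXCL14, HOXB5, KIFC2,
#' NODAL, RASSF5) carry two assays, one designed from the forward strand and
#' one from the reverse complement ("rc" suffix). Two recovery-control
#' assays (NSD1 for the 14-min bisulfite group, a HOXD9 promoter assay for
#' the 42-min group) are carried as metadata: they verify recovery of
#' amplifiable DNA and never enter the 19-marker scores.
#'
#' @section Panel configuration schema:
#' A YAML file with top-level keys `name`, `markers` and `control_assays`.
#' Each marker entry has `marker_id`, `gene` and a list `assays`; each assay
#' has `assay_id`, optional `aliases` (alternative spellings accepted on
#' input), `strand_variant` (`forward` or `reverse-complement`) and
#' `bisulfite_group` (`14min70C` or `42min80C`). See
#' `system.file("extdata", "default_panel.yaml", package = "methpanel")`.
#'
#' @name panel
NULL

# marker_id, gene, assay ids (1 or 2), aliases keyed by assay id
.default_panel_spec <- function() {
  list(
    list("ADCY4",  "ADCY4",   c("ADCY4")),
    list("AOX1",   "AOX1",    c("AOX1rc")),
    list("APC2",   "APC",     c("APC2"),   list(APC2 = "APC")),
    list("CXCL14", "CXCL14",  c("CXCL14", "CXCL14rc")),
    list("EPHX3",  "EPHX3",   c("EPHX3")),
    list("GFRA2",  "GFRA2",   c("GFRA2")),
    list("GSTP1",  "GSTP1",   c("GSTP1")),
    list("HEMK1",  "HEMK1",   c("HEMK1"),  list(HEMK1 = "HEMK1rc")),
    list("HOXA7",  "HOXA7",   c("HOXA7")),
    list("HOXB5",  "HOXB5",   c("HOXB5", "HOXB5rc")),
    list("HOXD10", "HOXD10",  c("HOXD10")),
    list("HOXD3a", "HOXD3",   c("HOXD3a")),
    list("HOXD3b", "HOXD3",   c("HOXD3b")),
    list("HOXD9",  "HOXD9",   c("HOXD9")),
    list("KIFC2",  "KIFC2",   c("KIFC2", "KIFC2rc")),
    list("MOXD1",  "MOXD1",   c("MOXD1")),
    list("NEUROG3","NEUROG3", c("NEUROG3")),
    list("NODAL",  "NODAL",   c("NODAL", "NODALrc")),
    list("RASSF5", "RASSF5",  c("RASSF5", "RASSF5rc"))
  )
}

# Markers validated previously in biopsy tissue run under the 42-min/80C
# bisulfite condition in the default config; the newer markers under
# 14-min/70C. Nominal metadata (per-assay assignment is configurable).
.bisulfite_42 <- c("ADCY4", "APC2", "CXCL14", "GFRA2", "GSTP1", "HEMK1",
                   "HOXB5", "HOXD9", "KIFC2", "MOXD1", "NEUROG3", "RASSF5")

#' Build the default 19-marker prostate panel
#'
#' @return A `meth_panel` object (see [load_panel()]).
#' @examples
#' p <- default_panel()
#' nrow(p$markers)  # 19
#' nrow(p$assays)   # 24
#' @export
default_panel <- function() {
  spec <- .default_panel_spec()
  markers <- data.frame(
    marker_id = vapply(spec, `[[`, "", 1),
    gene      = vapply(spec, `[[`, "", 2),
    n_assays  = vapply(spec, function(m) length(m[[3]]), 0L),
    stringsAsFactors = FALSE
  )
  rows <- lapply(spec, function(m) {
    ids <- m[[3]]
    aliases <- if (length(m) >= 4) m[[4]] else list()
    data.frame(
      assay_id  = ids,
      marker_id = m[[1]],
      strand_variant = ifelse(grepl("rc$", ids), "reverse-complement",
                              "forward"),
      bisulfite_group = if (m[[1]] %in% .bisulfite_42) "42min80C"
                        else "14min70C",
      alias = vapply(ids, function(a) aliases[[a]] %||% NA_character_, ""),
      stringsAsFactors = FALSE
    )
  })
  assays <- do.call(rbind, rows)
  rownames(assays) <- NULL
  controls <- data.frame(
    assay_id = c("NSD1", "HOXD9ctrl"),
    bisulfite_group = c("14min70C", "42min80C"),
    stringsAsFactors = FALSE
  )
  new_meth_panel(name = "prostate19", markers = markers, assays = assays,
                 control_assays = controls)
}

new_meth_panel <- function(name, markers, assays, control_assays) {
  panel <- structure(
    list(name = name, markers = markers, assays = assays,
         control_assays = control_assays),
    class = "meth_panel"
  )
  validate_panel(panel)
}

#' Validate a panel definition
#'
#' Checks the structural invariants of a `meth_panel`: unique assay ids,
#' every assay mapping to a known marker, each marker carrying one or two
#' assays, and consistency of the per-marker assay counts. The expected
#' totals (19 markers, 24 assays, 5 dual-assay markers for the default
#' panel) are properties of a particular panel, not of the class, so only
#' relational invariants are enforced here; [load_panel()] enforces the
#' declared counts when a config states them.
#'
#' @param panel a `meth_panel`.
#' @param n_markers,n_assays optional expected totals; validated when given.
#' @return the panel, invisibly usable, or an error naming the offender.
#' @export
validate_panel <- function(panel, n_markers = NULL, n_assays = NULL) {
  m <- panel$markers; a <- panel$assays
  dup <- a$assay_id[duplicated(a$assay_id)]
  if (length(dup))
    stopf("duplicate assay id(s): %s", paste(unique(dup), collapse = ", "))
  dupm <- m$marker_id[duplicated(m$marker_id)]
  if (length(dupm))
    stopf("duplicate marker id(s): %s", paste(unique(dupm), collapse = ", "))
  orphan <- setdiff(a$marker_id, m$marker_id)
  if (length(orphan))
    stopf("assay(s) reference unknown marker(s): %s",
          paste(orphan, collapse = ", "))
  counts <- table(factor(a$marker_id, levels = m$marker_id))
  if (any(counts == 0))
    stopf("marker(s) with no assay: %s",
          paste(names(counts)[counts == 0], collapse = ", "))
  if (any(counts > 2))
    stopf("marker(s) with more than 2 assays: %s",
          paste(names(counts)[counts > 2], collapse = ", "))
  if (!identical(as.integer(counts[m$marker_id]), as.integer(m$n_assays)))
    stopf("n_assays column inconsistent with assay table")
  if (!is.null(n_markers) && nrow(m) != n_markers)
    stopf("panel has %d markers, expected %d", nrow(m), n_markers)
  if (!is.null(n_assays) && nrow(a) != n_assays)
    stopf("panel has %d assays, expected %d", nrow(a), n_assays)
  clash <- intersect(panel$control_assays$assay_id, a$assay_id)
  if (length(clash))
    stopf("control assay id(s) clash with panel assays: %s",
          paste(clash, collapse = ", "))
  panel
}

#' Load a panel definition
#'
#' Reads and validates a panel configuration. With no argument the built-in
#' 19-marker prostate panel is returned. A YAML config (see [panel]) may
#' declare `n_markers` / `n_assays`; when present the loaded panel must
#' match them exactly.
#'
#' @param config path to a YAML panel config, or `NULL` for the default.
#' @return a `meth_panel`: list with `name`, `markers` (data frame
#'   `marker_id`, `gene`, `n_assays`), `assays` (data frame `assay_id`,
#'   `marker_id`, `strand_variant`, `bisulfite_group`, `alias`) and
#'   `control_assays`.
#' @examples
#' panel <- load_panel()
#' subset(panel$markers, n_assays == 2)$marker_id
#' @export
load_panel <- function(config = NULL) {
  if (is.null(config)) return(default_panel())
  if (is.character(config)) {
    if (!file.exists(config)) stopf("panel config not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$markers))
    stopf("panel config must be a list with a 'markers' entry")
  markers <- data.frame(
    marker_id = vapply(config$markers, function(m)
      m$marker_id %||% stopf("marker entry without marker_id"), ""),
    gene = vapply(config$markers, function(m) m$gene %||% NA_character_, ""),
    n_assays = vapply(config$markers, function(m) length(m$assays), 0L),
    stringsAsFactors = FALSE
  )
  arows <- lapply(config$markers, function(m) {
    if (is.null(m$assays) || !length(m$assays))
      stopf("marker %s has no assays", m$marker_id)
    do.call(rbind, lapply(m$assays, function(a) data.frame(
      assay_id = a$assay_id %||% stopf("assay without assay_id under %s",
                                       m$marker_id),
      marker_id = m$marker_id,
      strand_variant = a$strand_variant %||% "forward",
      bisulfite_group = a$bisulfite_group %||% NA_character_,
      alias = if (length(a$aliases)) paste(unlist(a$aliases),
                                           collapse = "|") else NA_character_,
      stringsAsFactors = FALSE
    )))
  })
  assays <- do.call(rbind, arows)
  rownames(assays) <- NULL
  bad <- setdiff(assays$strand_variant, c("forward", "reverse-complement"))
  if (length(bad)) stopf("unknown strand_variant: %s", paste(bad, collapse = ", "))
  controls <- if (length(config$control_assays)) {
    do.call(rbind, lapply(config$control_assays, function(a) data.frame(
      assay_id = a$assay_id, bisulfite_group = a$bisulfite_group %||% NA,
      stringsAsFactors = FALSE)))
  } else data.frame(assay_id = character(), bisulfite_group = character(),
                    stringsAsFactors = FALSE)
  panel <- new_meth_panel(config$name %||% "custom", markers, assays, controls)
  validate_panel(panel, n_markers = config$n_markers, n_assays = config$n_assays)
}

#' Serialize a panel to YAML
#'
#' Writes a config that [load_panel()] re-parses to an identical panel.
#'
#' @param panel a `meth_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cfg <- list(
    name = panel$name,
    n_markers = nrow(panel$markers),
    n_assays = nrow(panel$assays),
    markers = lapply(seq_len(nrow(panel$markers)), function(i) {
      m <- panel$markers[i, ]
      arows <- panel$assays[panel$assays$marker_id == m$marker_id, ,
                            drop = FALSE]
      list(
        marker_id = m$marker_id, gene = m$gene,
        assays = lapply(seq_len(nrow(arows)), function(j) {
          a <- arows[j, ]
          out <- list(assay_id = a$assay_id,
                      strand_variant = a$strand_variant,
                      bisulfite_group = a$bisulfite_group)
          if (!is.na(a$alias)) out$aliases <- strsplit(a$alias, "|",
                                                       fixed = TRUE)[[1]]
          out
        })
      )
    }),
    control_assays = lapply(seq_len(nrow(panel$control_assays)), function(i)
      as.list(panel$control_assays[i, ]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# canonical assay id lookup including aliases; names = accepted spellings
assay_alias_map <- function(panel) {
  map <- stats::setNames(panel$assays$assay_id, panel$assays$assay_id)
  has <- !is.na(panel$assays$alias)
  for (i in which(has)) {
    for (al in strsplit(panel$assays$alias[i], "|", fixed = TRUE)[[1]])
      map[al] <- panel$assays$assay_id[i]
  }
  map
}

#' @export
print.meth_panel <- function(x, ...) {
  dual <- x$markers$marker_id[x$markers$n_assays == 2]
  cat(sprintf("<meth_panel '%s'>: %d markers, %d assays (%d dual-assay: %s)\n",
              x$name, nrow(x$markers), nrow(x$assays), length(dual),
              paste(dual, collapse = ", ")))
  if (nrow(x$control_assays))
    cat("  control assays:", paste(x$control_assays$assay_id, collapse = ", "),
        "\n")
  invisible(x)
}
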