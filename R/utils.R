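# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero
#' (0.005 -> 0.01), the convention used for report tables. Base R's
#' `round()` rounds half to even, which differs on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.705, 0.8974), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# Run code with a temporarily seeded RNG, restoring global state afterwards.
# All stochastic entry points route their seed through this so that no call
# disturbs the caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Align a named vector `x` against named `labels`; both must cover the same
# patients. Unnamed vectors of equal length are taken as already aligned.
align_by_patient <- function(x, labels, xname = "calls", lname = "labels") {
  if (is.null(names(x)) || is.null(names(labels))) {
    if (length(x) != length(labels))
      stopf("%s and %s have different lengths (%d vs %d) and are unnamed",
            xname, lname, length(x), length(labels))
    return(list(x = x, labels = labels))
  }
  extra   <- setdiff(names(x), names(labels))
  missing <- setdiff(names(labels), names(x))
  if (length(extra) || length(missing))
    stopf("patient mismatch between %s and %s; only in %s: %s; only in %s: %s",
          xname, lname, xname,
          paste(extra, collapse = ", ") %||% "",
          lname, paste(missing, collapse = ", "))
  list(x = x[names(labels)], labels = labels)
}

check_binary_labels <- function(labels) {
  lab <- as.integer(labels)
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stopf("labels must be binary (0 = control, 1 = case)")
  lab
}
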