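#' IC50 label transforms
#'
#' Measured IC50 binding affinities (nM) span roughly \[0, 80000\], which is
#' numerically hostile for gradient training, so regression labels are the
#' natural logarithm of the IC50. `log_ic50()` clamps its input to at least
#' 1 nM before taking the log (the log is undefined at 0 and values below
#' 1 nM are beyond assay resolution), so labels are always finite and
#' non-negative. `ic50_from_log()` maps predictions back to the nM scale,
#' clamped to the measurable range \[0, 80000\].
#'
#' @param ic50 Numeric vector of IC50 values in nM, all >= 0.
#' @param log_ic50 Numeric vector of log-scale affinities.
#' @return Numeric vector of the same length.
#' @examples
#' log_ic50(500)          # ~ 6.2146, the conventional binding threshold
#' ic50_from_log(log(500))
#' @export
log_ic50 <- function(ic50) {
  stopifnot(is.numeric(ic50))
  if (any(ic50 < 0, na.rm = TRUE)) {
    abort("IC50 values must be non-negative", class = "panbinder_domain_error")
  }
  log(pmax(ic50, 1))
}

#' @rdname log_ic50
#' @export
ic50_from_log <- function(log_ic50) {
  stopifnot(is.numeric(log_ic50), all(is.finite(log_ic50) | is.na(log_ic50)))
  pmin(pmax(exp(log_ic50), 0), 80000)
}

#' Binary binding labels
#'
#' `binarize_ic50()` applies the standard 500 nM convention: a peptide is
#' labelled a binder (1) when its IC50 is at most 500 nM, else a non-binder
#' (0); the boundary value 500 itself counts as binding. `binarize_t_half()`
#' converts dissociation half-life measurements: a measured half-life below
#' 120 minutes indicates the binding state (the convention used when scoring
#' half-life benchmark datasets).
#'
#' @param ic50 Numeric vector of IC50 values in nM, >= 0.
#' @param minutes Numeric vector of half-life measurements in minutes, >= 0.
#' @return Integer vector of 0/1 labels.
#' @examples
#' binarize_ic50(c(0.5, 500, 80000))
#' binarize_t_half(c(119, 120))
#' @export
binarize_ic50 <- function(ic50) {
  stopifnot(is.numeric(ic50))
  if (any(ic50 < 0, na.rm = TRUE)) {
    abort("IC50 values must be non-negative", class = "panbinder_domain_error")
  }
  as.integer(ic50 <= 500)
}

#' @rdname binarize_ic50
#' @export
binarize_t_half <- function(minutes) {
  stopifnot(is.numeric(minutes))
  if (any(minutes < 0, na.rm = TRUE)) {
    abort("half-life values must be non-negative", class = "panbinder_domain_error")
  }
  as.integer(minutes < 120)
}
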