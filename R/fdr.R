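#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment. Input p-values must be valid probabilities; `NaN`
#' is rejected rather than propagated so that silent misuse upstream cannot
#' masquerade as non-significance.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, in input order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p))) abort("NaN/NA p-values are not allowed.")
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1].")
  p.adjust(p, method = "BH")
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR discovery flags
#'
#' The adaptive two-stage linear step-up procedure: stage one runs a BH
#' step-up at the deflated level q' = Q / (1 + Q) to estimate the number of
#' true nulls m0 = m - r1 (r1 = stage-one rejections); stage two reruns the
#' step-up at level q' * m / m0. With r1 = 0 nothing is flagged; with
#' r1 = m everything is. When stage one estimates m0 = m the procedure
#' coincides with plain BH at q'.
#'
#' @param p Raw p-values in (0, 1].
#' @param q Target false discovery rate Q (default 0.01).
#' @return Logical discovery flags in input order, with attribute `m0`
#'   (estimated number of true nulls).
#' @export
two_stage_bky <- function(p, q = 0.01) {
  if (!length(p)) return(logical(0))
  if (any(is.na(p))) abort("NaN/NA p-values are not allowed.")
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1].")
  stopifnot_scalar_number(q, "q", lower = 0, upper = 1)
  m <- length(p)
  q1 <- q / (1 + q)
  adj <- p.adjust(p, method = "BH")
  r1 <- sum(adj <= q1)
  if (r1 == 0L) {
    flags <- rep(FALSE, m)
    attr(flags, "m0") <- m
    return(flags)
  }
  if (r1 == m) {
    flags <- rep(TRUE, m)
    attr(flags, "m0") <- 0L
    return(flags)
  }
  m0 <- m - r1
  flags <- adj <= q1 * m / m0
  attr(flags, "m0") <- m0
  flags
}
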