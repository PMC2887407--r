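#' Date a gene duplication from synonymous distances
#'
#' Molecular-clock dating: an ortholog pair whose species split
#' \code{T_calibration} million years ago calibrates the synonymous rate
#' \eqn{r = d_S^{ortholog} / (2 T)}, and the duplication age follows as
#' \eqn{t = d_S^{paralog} / (2 r) = d_S^{paralog} \cdot T /
#' d_S^{ortholog}}.
#'
#' @param dS_ortholog synonymous distance between orthologs of the
#'   calibrating species pair (> 0).
#' @param dS_paralog synonymous distance between the two paralogs (> 0).
#' @param T_calibration calibration split time in million years (> 0).
#' @return list of class \code{clock_estimate}: \code{rate} (synonymous
#'   substitutions per site per MY), \code{t_duplication} (MYA, unrounded),
#'   \code{t_duplication_rounded} (nearest integer), and the echoed inputs.
#' @examples
#' clock_date(0.388, 0.592, 50)$t_duplication_rounded  # 76
#' @export
clock_date <- function(dS_ortholog, dS_paralog, T_calibration) {
  vals <- c(dS_ortholog, dS_paralog, T_calibration)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs must be finite and > 0")
  rate <- dS_ortholog / (2 * T_calibration)
  t_dup <- dS_paralog / (2 * rate)
  structure(list(rate = rate, t_duplication = t_dup,
                 t_duplication_rounded = round(t_dup),
                 dS_ortholog = dS_ortholog, dS_paralog = dS_paralog,
                 T_calibration = T_calibration),
            class = "clock_estimate")
}

#' @export
print.clock_estimate <- function(x, ...) {
  cat(sprintf(
    "duplication age: %.1f MYA (~%d MYA; rate %.3g syn subs/site/MY)\n",
    x$t_duplication, x$t_duplication_rounded, x$rate))
  invisible(x)
}
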