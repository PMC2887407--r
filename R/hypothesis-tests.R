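#' Likelihood ratio test between two nested codon-model fits
#'
#' \eqn{2\Delta L = 2(lnL_{alt} - lnL_{null})}, compared to a chi-square
#' distribution with degrees of freedom equal to the difference in parameter
#' counts. A negative statistic (possible when the models are not truly
#' nested, or the null was fitted better by chance of optimisation) is
#' reported with a warning flag and p = 1.
#'
#' @param fit_null,fit_alt \code{codon_fit} objects, or plain numeric
#'   log-likelihoods (in which case \code{df} is required).
#' @param df degrees of freedom; defaults to the difference of the fits'
#'   \code{n_params}.
#' @return list of class \code{lrt_result}: \code{lnL_null}, \code{lnL_alt},
#'   \code{stat}, \code{df}, \code{p_value}, \code{negative} flag.
#' @examples
#' lrt(-5020.93, -5015.74, df = 1)$stat  # 10.38
#' @export
lrt <- function(fit_null, fit_alt, df = NULL) {
  ln0 <- if (inherits(fit_null, "codon_fit")) fit_null$lnL else fit_null
  ln1 <- if (inherits(fit_alt, "codon_fit")) fit_alt$lnL else fit_alt
  if (is.null(df)) {
    if (!inherits(fit_null, "codon_fit") || !inherits(fit_alt, "codon_fit"))
      stop("df must be given when fits are plain log-likelihoods")
    df <- fit_alt$n_params - fit_null$n_params
  }
  if (df < 1L) stop("alternative model must have more parameters (df >= 1)")
  stat <- 2 * (ln1 - ln0)
  negative <- stat < 0
  if (negative) warning("negative LRT statistic (", round(stat, 4),
                        "): models may not be nested; p set to 1")
  p <- if (negative) 1 else chi2_pvalue(stat, df)
  structure(list(lnL_null = ln0, lnL_alt = ln1, stat = stat, df = df,
                 p_value = p, negative = negative),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2dL = %.4f, df = %d, p = %.4g %s\n",
              x$stat, x$df, x$p_value, significance_stars(x$p_value)))
  invisible(x)
}

#' Upper-tail chi-square p-value
#'
#' @param stat non-negative test statistic.
#' @param df degrees of freedom (positive integer).
#' @return upper-tail probability.
#' @examples
#' chi2_pvalue(4.83, 1)  # 0.028 to 3 d.p.
#' @export
chi2_pvalue <- function(stat, df) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(stat < 0)) stop("statistic must be >= 0")
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Tajima's one-degree relative rate test
#'
#' Compares the substitution rates of two ingroup sequences against an
#' outgroup from unique-difference counts at nucleotide sites where all
#' three sequences are resolved: \code{m1} counts sites where only sequence
#' A differs (A != B and B == outgroup), \code{m2} sites where only B
#' differs. Under rate equality m1 and m2 have equal expectation, and
#' \eqn{(m_1 - m_2)^2 / (m_1 + m_2)} is asymptotically chi-square with 1
#' degree of freedom. The reported \code{ratio} is m1/m2, the rate ratio of
#' lineage A to lineage B in unique-difference counts.
#'
#' @param a,b,outgroup aligned nucleotide strings of equal length; positions
#'   with a gap or N in any of the three are dropped.
#' @return list of class \code{rrt_result}: \code{m1}, \code{m2},
#'   \code{ratio}, \code{chi2}, \code{p_value}, \code{undefined} (TRUE when
#'   m1 + m2 = 0, in which case ratio, chi2 and p are NA).
#' @export
tajima_rrt <- function(a, b, outgroup) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  vo <- strsplit(toupper(outgroup), "")[[1]]
  if (length(unique(c(length(va), length(vb), length(vo)))) != 1L)
    stop("sequences must be aligned to equal length")
  nuc <- c("A", "C", "G", "T")
  ok <- va %in% nuc & vb %in% nuc & vo %in% nuc
  m1 <- sum(ok & va != vb & vb == vo)
  m2 <- sum(ok & vb != va & va == vo)
  if (m1 + m2 == 0L)
    return(structure(list(m1 = m1, m2 = m2, ratio = NA_real_,
                          chi2 = NA_real_, p_value = NA_real_,
                          undefined = TRUE), class = "rrt_result"))
  chi2 <- (m1 - m2)^2 / (m1 + m2)
  structure(list(m1 = m1, m2 = m2,
                 ratio = if (m2 > 0) m1 / m2 else Inf,
                 chi2 = chi2, p_value = chi2_pvalue(chi2, 1),
                 undefined = FALSE),
            class = "rrt_result")
}

#' @export
print.rrt_result <- function(x, ...) {
  if (x$undefined) cat("relative rate test: undefined (no unique differences)\n")
  else cat(sprintf(
    "relative rate test: m1 = %d, m2 = %d, ratio = %.3f, chi2 = %.3f, p = %.3f %s\n",
    x$m1, x$m2, x$ratio, x$chi2, x$p_value, significance_stars(x$p_value)))
  invisible(x)
}

#' Welch two-sample comparison of per-sequence statistics
#'
#' Unequal-variance t-test on two groups of per-sequence values (GC3, ENC,
#' dN, dS, ...). Degenerate input with zero variance in both groups and
#' equal means returns t = 0, p = 1 rather than an error.
#'
#' @param values_a,values_b numeric vectors, at least 2 values each.
#' @return list: \code{mean_a}, \code{mean_b}, \code{t_stat}, \code{df},
#'   \code{p_value}.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need at least 2 values per group")
  res <- tryCatch(stats::t.test(values_a, values_b, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    # constant data: equal means -> no evidence; unequal -> infinite t
    if (isTRUE(all.equal(mean(values_a), mean(values_b))))
      return(list(mean_a = mean(values_a), mean_b = mean(values_b),
                  t_stat = 0, df = NA_real_, p_value = 1))
    return(list(mean_a = mean(values_a), mean_b = mean(values_b),
                t_stat = Inf, df = NA_real_, p_value = 0))
  }
  list(mean_a = mean(values_a), mean_b = mean(values_b),
       t_stat = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Significance stars
#'
#' \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05, else empty.
#'
#' @param p p-value(s).
#' @return character vector of star strings.
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) ""
    else if (x < 0.001) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else ""
  }, character(1))
}
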