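#' Effective number of codons (Wright's ENC)
#'
#' Codon-usage bias of a single coding sequence, ranging from 20 (one codon
#' per amino acid: maximal bias) to 61 (uniform use of all synonymous
#' codons). For an amino acid with k synonymous codons observed n >= 2 times
#' with usage proportions p_i, the codon homozygosity is
#' \eqn{F = (n \sum p_i^2 - 1)/(n - 1)}; class means are taken over amino
#' acids within each degeneracy class (2-, 3-, 4-, 6-fold), and
#' \deqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#' Ile is the sole 3-fold family; Leu, Ser and Arg are kept as intact 6-fold
#' families. A missing 3-fold mean is imputed as
#' \eqn{(\bar F_2 + \bar F_4)/2}; if any other class has no amino acid with
#' n >= 2, the formula is reduced to the observed classes, scaled to the
#' full 61-codon range by \eqn{ENC = 61 \cdot (2 + \sum m_k) / (2 +
#' \sum m_k / \bar F_k)} over the available classes, and the result is
#' flagged. Values above 61 are clamped to 61 with a flag.
#'
#' @param seq a nucleotide string (length divisible by 3), a character
#'   vector of codons, or a single-sequence \code{codon_alignment}.
#' @param code a \code{genetic_code}.
#' @return list of class \code{enc_result}: \code{enc}, \code{F_bar} (named
#'   by class 2/3/4/6), \code{n_codons_used} (codons counted per class),
#'   \code{clamped}, \code{reduced}, \code{undefined}.
#' @export
enc <- function(seq, code = the_code()) {
  cods <- if (inherits(seq, "codon_alignment")) {
    if (length(seq$names) != 1L) stop("enc() takes one sequence at a time")
    split_codons(seq$sequences[1])
  } else if (length(seq) == 1L) split_codons(toupper(seq)) else toupper(seq)
  idx <- codon_index(cods, code)
  cods <- cods[!is.na(idx)]
  if (length(cods) == 0L)
    return(structure(list(enc = NA_real_, F_bar = NULL, n_codons_used = NULL,
                          clamped = FALSE, reduced = FALSE, undefined = TRUE),
                     class = "enc_result"))
  aa <- code$codon_to_aa[cods]
  deg <- code$degeneracy_class[cods]
  # per amino acid homozygosity, n >= 2 required
  F_aa <- list()
  for (a in unique(aa)) {
    k <- deg[match(a, aa)]
    if (k == 1L) next  # Met, Trp contribute the constant 2
    n <- sum(aa == a)
    if (n < 2L) next
    p <- as.numeric(table(cods[aa == a])) / n
    F_aa[[a]] <- c(F = (n * sum(p^2) - 1) / (n - 1), k = unname(k), n = n)
  }
  if (length(F_aa) == 0L)
    return(structure(list(enc = NA_real_, F_bar = NULL, n_codons_used = NULL,
                          clamped = FALSE, reduced = FALSE, undefined = TRUE),
                     class = "enc_result"))
  tab <- do.call(rbind, F_aa)
  classes <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)  # amino acids per class
  F_bar <- n_used <- stats::setNames(rep(NA_real_, 4), names(classes))
  for (k in names(classes)) {
    sel <- tab[, "k"] == as.numeric(k)
    if (any(sel)) {
      # guard F = 0 (possible at small n with evenly split usage)
      F_bar[k] <- max(mean(tab[sel, "F"]), 1e-6)
      n_used[k] <- sum(tab[sel, "n"])
    }
  }
  reduced <- FALSE
  if (is.na(F_bar["3"]) && !is.na(F_bar["2"]) && !is.na(F_bar["4"]))
    F_bar["3"] <- (F_bar["2"] + F_bar["4"]) / 2
  if (anyNA(F_bar)) {
    # reduced formula: a class with no usable amino acid borrows the mean
    # inverse homozygosity of the observed classes
    reduced <- TRUE
    ok <- !is.na(F_bar)
    enc_val <- 2 + sum(classes[ok] / F_bar[ok]) +
      sum(classes[!ok]) * mean(1 / F_bar[ok])
  } else {
    enc_val <- 2 + 9 / F_bar["2"] + 1 / F_bar["3"] + 5 / F_bar["4"] +
      3 / F_bar["6"]
  }
  clamped <- enc_val > 61
  if (clamped) enc_val <- 61
  structure(list(enc = unname(enc_val), F_bar = F_bar,
                 n_codons_used = n_used, clamped = clamped,
                 reduced = reduced, undefined = FALSE),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  if (x$undefined) cat("ENC: undefined (sequence too short)\n")
  else cat(sprintf("ENC = %.2f%s%s\n", x$enc,
                   if (x$clamped) " (clamped to 61)" else "",
                   if (x$reduced) " (reduced formula)" else ""))
  invisible(x)
}

#' Per-sequence ENC and GC3 table
#'
#' @param aln a \code{codon_alignment}.
#' @return data.frame: \code{seq_id}, \code{enc}, \code{gc3},
#'   \code{n_codons}.
#' @export
enc_table <- function(aln) {
  gc <- gc_content(aln)
  vals <- vapply(aln$sequences, function(s) enc(s)$enc, numeric(1))
  data.frame(seq_id = aln$names, enc = unname(vals), gc3 = gc$gc3,
             n_codons = aln$n_codons, stringsAsFactors = FALSE)
}
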