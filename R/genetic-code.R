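#' Standard genetic code machinery
#'
#' Builds the lookup tables every codon-level analysis in this package rests
#' on: the 64 trinucleotides, their amino-acid translations under the
#' standard nuclear code, the ordered list of the 61 sense codons, and the
#' synonymous-family (degeneracy) class of each sense codon.
#'
#' Codons are ordered T, C, A, G by position (the conventional codon-table
#' order), so the 61 sense codons have a fixed, reproducible ordering that
#' the rate-matrix and simulation code index into.
#'
#' @return An object of class \code{genetic_code}: a list with elements
#'   \item{codons}{all 64 trinucleotides in TCAG order}
#'   \item{codon_to_aa}{named character vector, codon -> one-letter amino
#'     acid, \code{"*"} for stop}
#'   \item{sense_codons}{the 61 non-stop codons, in codon-table order}
#'   \item{stop_codons}{the 3 stop codons}
#'   \item{degeneracy_class}{named integer vector over the sense codons:
#'     the size of the codon family of the encoded amino acid
#'     (1, 2, 3, 4 or 6)}
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons)  # 61
#' gc$codon_to_aa["ATG"]    # "M"
#' @export
genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(
    outer(bases, bases, function(a, b) paste0(a, b)),
    bases, paste0
  ))
  # outer() above varies the *first* factor fastest; rebuild explicitly in
  # slow-to-fast (pos1, pos2, pos3) order to get the canonical table layout.
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  aa <- Biostrings::GENETIC_CODE[codons]
  names(aa) <- codons
  sense <- codons[aa != "*"]
  fam <- table(aa[aa != "*"])
  deg <- as.integer(fam[aa[sense]])
  names(deg) <- sense
  structure(
    list(
      codons = codons,
      codon_to_aa = aa,
      sense_codons = sense,
      stop_codons = codons[aa == "*"],
      degeneracy_class = deg
    ),
    class = "genetic_code"
  )
}

# Cached copy: the code table never changes within a session.
the_code <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- genetic_code()
    cache
  }
})

#' Map codons to sense-codon indices
#'
#' @param codons character vector of trinucleotides.
#' @param code a \code{genetic_code} object.
#' @return integer indices into \code{code$sense_codons}; \code{NA} for
#'   codons containing gaps or N, and for stop codons.
#' @keywords internal
codon_index <- function(codons, code = the_code()) {
  match(codons, code$sense_codons)
}

#' Is a codon a stop codon?
#' @keywords internal
#' @noRd
is_stop_codon <- function(codons, code = the_code()) {
  codons %in% code$stop_codons
}

# Split a nucleotide string into codons.
#' @noRd
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Transition (purine<->purine, pyrimidine<->pyrimidine) indicator for a
# pair of single nucleotides.
#' @noRd
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}
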