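#' Codon substitution model parameters
#'
#' Bundles the transition/transversion rate ratio kappa and the equilibrium
#' codon frequencies pi over the 61 sense codons of the standard code.
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param codon_freqs numeric vector of length 61 on the simplex, named or
#'   ordered as \code{genetic_code()$sense_codons}.
#' @param freq_mode how the frequencies were obtained: \code{"equal"},
#'   \code{"F3x4"} or \code{"empirical-codon"} (metadata only).
#' @return object of class \code{codon_model}.
#' @export
codon_model <- function(kappa = 2, codon_freqs = equal_frequencies(),
                        freq_mode = "custom") {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  code <- the_code()
  if (!is.null(names(codon_freqs)))
    codon_freqs <- codon_freqs[code$sense_codons]
  if (length(codon_freqs) != 61L || anyNA(codon_freqs))
    stop("codon_freqs must cover the 61 sense codons")
  if (any(codon_freqs < 0) || abs(sum(codon_freqs) - 1) > 1e-12)
    stop("codon_freqs must be non-negative and sum to 1 (within 1e-12)")
  structure(list(kappa = kappa,
                 codon_freqs = stats::setNames(codon_freqs, code$sense_codons),
                 freq_mode = freq_mode),
            class = "codon_model")
}

#' Equal sense-codon frequencies
#' @return numeric vector of length 61, each 1/61.
#' @export
equal_frequencies <- function() {
  code <- the_code()
  stats::setNames(rep(1 / 61, 61), code$sense_codons)
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies (gaps/N excluded) multiplied
#' across the three codon positions, restricted to the 61 sense codons and
#' renormalised.
#'
#' @param aln a \code{codon_alignment}.
#' @return numeric vector of length 61 on the simplex.
#' @export
f3x4_frequencies <- function(aln) {
  b <- unlist(strsplit(aln$sequences, "", fixed = TRUE), use.names = FALSE)
  pos <- rep_len(rep_len(1:3, aln$length_nt), length(b))
  f <- matrix(0, 3, 4, dimnames = list(NULL, c("T", "C", "A", "G")))
  for (p in 1:3) {
    bb <- b[pos == p]
    bb <- bb[bb %in% c("T", "C", "A", "G")]
    if (length(bb) == 0L) stop("no resolved bases at codon position ", p)
    tab <- table(factor(bb, levels = c("T", "C", "A", "G")))
    f[p, ] <- as.numeric(tab) / sum(tab)
  }
  frequencies_from_positions(f)
}

# pi over sense codons from a 3x4 matrix of position-specific nucleotide
# frequencies (columns T, C, A, G).
#' @noRd
frequencies_from_positions <- function(f) {
  code <- the_code()
  pis <- vapply(code$sense_codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    f[1, b[1]] * f[2, b[2]] * f[3, b[3]]
  }, numeric(1))
  # floor: a base absent at one position on a short alignment must not give
  # codons zero equilibrium frequency (breaks reversible decomposition and
  # zeroes the likelihood of observed states)
  pis <- pmax(pis / sum(pis), 1e-8)
  pis / sum(pis)
}

#' Empirical codon frequencies from an alignment
#'
#' Observed sense-codon proportions; a half-count is added to every sense
#' codon so unobserved codons keep positive equilibrium frequency.
#'
#' @param aln a \code{codon_alignment}.
#' @return numeric vector of length 61 on the simplex.
#' @export
empirical_codon_frequencies <- function(aln) {
  code <- the_code()
  m <- codon_matrix(aln)
  idx <- codon_index(m, code)
  cnt <- tabulate(idx[!is.na(idx)], nbins = 61L) + 0.5
  stats::setNames(cnt / sum(cnt), code$sense_codons)
}

# Static single-step structure over the 61 sense codons: for each ordered
# pair differing at exactly one position, the row (i), column (j), and
# multiplier type 1..4 = syn-tv, syn-ts, nonsyn-tv, nonsyn-ts.
#' @noRd
codon_pair_structure <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- the_code()
    sense <- code$sense_codons
    aa <- code$codon_to_aa[sense]
    chars <- do.call(rbind, strsplit(sense, ""))
    ii <- jj <- tt <- integer(0)
    for (i in seq_len(61L)) {
      for (pos in 1:3) {
        for (b in setdiff(c("T", "C", "A", "G"), chars[i, pos])) {
          nb <- chars[i, ]; nb[pos] <- b
          j <- match(paste(nb, collapse = ""), sense)
          if (is.na(j)) next  # stop codon
          ts <- is_transition(chars[i, pos], b)
          syn <- aa[i] == aa[j]
          ii <- c(ii, i); jj <- c(jj, j)
          tt <- c(tt, 1L + ts + 2L * !syn)
        }
      }
    }
    cache <<- list(i = ii, j = jj, type = tt)
    cache
  }
})

#' Goldman-Yang codon rate matrix
#'
#' Off-diagonal entries are nonzero only between codons differing at a
#' single position: \eqn{q_{ij} = \pi_j}, multiplied by \eqn{\kappa} for
#' transitions and \eqn{\omega} for nonsynonymous changes. The diagonal
#' makes rows sum to zero, and the matrix is scaled so
#' \eqn{-\sum_i \pi_i q_{ii} = 1}, i.e. branch lengths are expected codon
#' substitutions per codon.
#'
#' @param model a \code{codon_model} (kappa, pi).
#' @param omega nonsynonymous/synonymous rate ratio, >= 0.
#' @return 61x61 generator matrix with \code{dimnames} the sense codons.
#' @export
build_rate_matrix <- function(model, omega) {
  if (!is.finite(omega) || omega < 0) stop("omega must be >= 0")
  code <- the_code()
  st <- codon_pair_structure()
  pi <- unname(model$codon_freqs)
  mult <- c(1, model$kappa, omega, omega * model$kappa)[st$type]
  Q <- matrix(0, 61, 61, dimnames = list(code$sense_codons, code$sense_codons))
  Q[cbind(st$i, st$j)] <- pi[st$j] * mult
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (zero total rate)")
  Q / scale
}

# Spectral decomposition of a reversible generator. Symmetrise with
# diag(sqrt(pi)): S = D Q D^-1 is symmetric, so Q = U diag(lambda) Uinv with
# U = D^-1 V, Uinv = t(V) D. P(t) = U diag(exp(lambda t)) Uinv, computed
# with two 61x61 products per t.
#' @noRd
decompose_generator <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2  # symmetrise numerically
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors / d, Uinv = t(e$vectors) * rep(d, each = 61L),
       lambda = e$values)
}

#' @noRd
pmat_from_decomp <- function(dec, t) {
  P <- dec$U %*% (exp(dec$lambda * t) * dec$Uinv)
  P[P < 0] <- 0
  P
}

#' Transition probability matrix of a codon generator
#'
#' \eqn{P(t) = e^{Qt}} via the spectral decomposition of the reversible
#' generator. Tiny negative entries from roundoff are clamped to 0.
#'
#' @param Q a generator from [build_rate_matrix()].
#' @param t branch length >= 0 (expected codon substitutions per codon).
#' @param model the \code{codon_model} that built \code{Q} (supplies pi for
#'   the symmetrisation); if omitted, pi is recovered from the stationary
#'   distribution assumption via detailed balance.
#' @return 61x61 stochastic matrix.
#' @export
transition_probabilities <- function(Q, t, model = NULL) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  if (t == 0) return(diag(61L))
  pi <- if (!is.null(model)) unname(model$codon_freqs) else stationary_of(Q)
  pmat_from_decomp(decompose_generator(Q, pi), t)
}

# Stationary distribution of a reversible single-step generator, recovered
# from detailed balance along a spanning set of connected pairs.
#' @noRd
stationary_of <- function(Q) {
  e <- eigen(t(Q))
  k <- which.min(abs(e$values))
  v <- abs(Re(e$vectors[, k]))
  v / sum(v)
}
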