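#' Nei-Gojobori synonymous and nonsynonymous site counts of one codon
#'
#' For each of the three codon positions the synonymous fraction is the
#' number of the three possible single-nucleotide changes that are
#' synonymous, divided by the number of changes counted; changes creating a
#' stop codon are excluded from both numerator and denominator. Synonymous
#' and nonsynonymous site counts always sum to exactly 3.
#'
#' @param codon a sense codon (3-letter string over ACGT).
#' @param code a \code{genetic_code}.
#' @return numeric vector \code{c(syn, nonsyn)}.
#' @examples
#' ng86_sites("TTT")  # syn = 1/3
#' @export
ng86_sites <- function(codon, code = the_code()) {
  codon <- toupper(codon)
  if (is.na(codon_index(codon, code)))
    stop("not a sense codon: ", codon)
  aa <- code$codon_to_aa[[codon]]
  b <- strsplit(codon, "", fixed = TRUE)[[1]]
  syn <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("T", "C", "A", "G"), b[pos])
    n_syn <- 0L; n_counted <- 0L
    for (a in alts) {
      nb <- b; nb[pos] <- a
      naa <- code$codon_to_aa[[paste(nb, collapse = "")]]
      if (naa == "*") next  # change to stop: excluded from denominator
      n_counted <- n_counted + 1L
      if (naa == aa) n_syn <- n_syn + 1L
    }
    if (n_counted > 0L) syn <- syn + n_syn / n_counted
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# Synonymous/nonsynonymous step counts between two sense codons, averaged
# over all minimal substitution pathways; pathways passing through a stop
# codon are excluded. Returns c(sd, nd, n_paths_valid) with NA counts when
# every pathway is blocked by a stop.
#' @noRd
ng86_path_counts <- function(a, b, code = the_code()) {
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  nd_tot <- length(diff_pos)
  if (nd_tot == 0L) return(c(sd = 0, nd = 0, valid = 1))
  perms <- all_permutations(diff_pos)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sd_sum <- 0; nd_sum <- 0; n_valid <- 0L
  for (p in seq_len(nrow(perms))) {
    cur <- av
    sd_p <- 0L; nd_p <- 0L
    ok <- TRUE
    for (pos in perms[p, ]) {
      prev_aa <- code$codon_to_aa[[paste(cur, collapse = "")]]
      cur[pos] <- bv[pos]
      nxt <- paste(cur, collapse = "")
      nxt_aa <- code$codon_to_aa[[nxt]]
      if (nxt_aa == "*") { ok <- FALSE; break }
      if (nxt_aa == prev_aa) sd_p <- sd_p + 1L else nd_p <- nd_p + 1L
    }
    if (ok) {
      n_valid <- n_valid + 1L
      sd_sum <- sd_sum + sd_p
      nd_sum <- nd_sum + nd_p
    }
  }
  if (n_valid == 0L) return(c(sd = NA_real_, nd = NA_real_, valid = 0))
  c(sd = sd_sum / n_valid, nd = nd_sum / n_valid, valid = n_valid)
}

# Cached per-codon site counts (61 x 2) and pathway-averaged difference
# counts between every ordered pair of sense codons (61 x 61 matrices SD,
# ND; NA where every minimal pathway crosses a stop).
#' @noRd
ng86_tables <- local({
  cache <- NULL
  function(code = the_code()) {
    if (!is.null(cache)) return(cache)
    sites <- t(vapply(code$sense_codons, ng86_sites, numeric(2), code = code))
    SD <- ND <- matrix(0, 61, 61)
    for (i in 1:61) for (j in 1:61) {
      if (i == j) next
      cnt <- ng86_path_counts(code$sense_codons[i], code$sense_codons[j],
                              code)
      SD[i, j] <- cnt[["sd"]]
      ND[i, j] <- cnt[["nd"]]
    }
    cache <<- list(sites = sites, SD = SD, ND = ND)
    cache
  }
})

# All permutations of a short vector (at most 3 elements here).
#' @noRd
all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Nei-Gojobori (1986) pairwise dN and dS
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (averaged over all minimal substitution
#' pathways for multi-hit codons, excluding pathways through stop codons),
#' then applies the Jukes-Cantor correction
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4p}{3})} to the proportions
#' \eqn{p_S = S_d/S} and \eqn{p_N = N_d/N}.
#'
#' Codons containing a gap or N in either sequence are dropped pairwise.
#' When \eqn{p \ge 3/4} the corrected distance is undefined and flagged
#' saturated. When \eqn{d_S = 0} the ratio \code{omega} is reported as
#' \code{NA}, never infinity.
#'
#' @param a,b codon sequences: nucleotide strings of equal length divisible
#'   by 3, or equal-length character vectors of codons.
#' @param code a \code{genetic_code}.
#' @return list of class \code{pairwise_divergence}: \code{S_sites},
#'   \code{N_sites}, \code{Sd}, \code{Nd}, \code{pS}, \code{pN}, \code{dN},
#'   \code{dS}, \code{omega}, \code{n_codons} (compared), \code{saturated}.
#' @examples
#' d <- ng86_pair("TTTAAA", "TTCAAA")  # one synonymous change
#' d$Nd  # 0
#' @export
ng86_pair <- function(a, b, code = the_code()) {
  ca <- if (length(a) == 1L) split_codons(toupper(a)) else toupper(a)
  cb <- if (length(b) == 1L) split_codons(toupper(b)) else toupper(b)
  if (length(ca) != length(cb)) stop("unequal codon counts")
  ia <- codon_index(ca, code)
  ib <- codon_index(cb, code)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) stop("no comparable codons after pairwise deletion")
  ia <- ia[keep]; ib <- ib[keep]
  tb <- ng86_tables(code)
  sd_i <- tb$SD[cbind(ia, ib)]
  nd_i <- tb$ND[cbind(ia, ib)]
  usable <- is.finite(sd_i)
  dropped <- sum(!usable)
  S <- sum((tb$sites[ia[usable], 1] + tb$sites[ib[usable], 1]) / 2)
  N <- sum((tb$sites[ia[usable], 2] + tb$sites[ib[usable], 2]) / 2)
  Sd <- sum(sd_i[usable])
  Nd <- sum(nd_i[usable])
  if (dropped > 0L)
    warning(dropped, " codon(s) dropped: every minimal pathway crosses a stop")
  n_used <- sum(keep) - dropped
  if (n_used == 0L) stop("no comparable codons after pathway exclusion")
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(
    list(S_sites = unname(S), N_sites = unname(N),
         Sd = unname(Sd), Nd = unname(Nd),
         pS = unname(pS), pN = unname(pN),
         dN = unname(dN), dS = unname(dS), omega = omega,
         n_codons = n_used,
         saturated = c(S = pS >= 0.75, N = pN >= 0.75)),
    class = "pairwise_divergence"
  )
}

#' Jukes-Cantor nucleotide distance
#'
#' \eqn{K = -\frac{3}{4}\log(1 - \frac{4p}{3})} where p is the mismatch
#' proportion over positions where both sequences have a resolved base
#' (gap/N positions dropped pairwise).
#'
#' @param a,b nucleotide strings of equal length.
#' @return K, or \code{NA} with attribute \code{saturated = TRUE} when
#'   \eqn{p \ge 3/4}.
#' @export
jc_distance <- function(a, b) {
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(va) != length(vb)) stop("unequal sequence lengths")
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable positions")
  p <- mean(va[ok] != vb[ok])
  if (p >= 0.75) return(structure(NA_real_, saturated = TRUE))
  -0.75 * log(1 - 4 * p / 3)
}

#' Mean within-group divergence
#'
#' Arithmetic mean of all within-group pairwise NG86 dN and dS, and the
#' overall ratio \code{mean_dN / mean_dS}.
#'
#' @param aln a \code{codon_alignment}.
#' @param group character vector of at least 2 sequence ids in \code{aln}.
#' @param code a \code{genetic_code}.
#' @return list with \code{mean_dN}, \code{mean_dS}, \code{overall_omega},
#'   \code{n_pairs}, and per-pair vectors \code{dN}, \code{dS}.
#' @export
mean_divergence <- function(aln, group, code = the_code()) {
  idx <- match(group, aln$names)
  if (anyNA(idx)) stop("unknown sequence id(s): ",
                       paste(group[is.na(idx)], collapse = ", "))
  if (length(idx) < 2L) stop("need at least 2 sequences in the group")
  prs <- utils::combn(idx, 2)
  dN <- dS <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    d <- ng86_pair(aln$sequences[prs[1, k]], aln$sequences[prs[2, k]], code)
    dN[k] <- d$dN; dS[k] <- d$dS
  }
  ok <- is.finite(dN) & is.finite(dS)
  if (!any(ok)) stop("all pairs saturated; mean divergence undefined")
  if (any(!ok)) warning(sum(!ok), " saturated pair(s) excluded from means")
  m_dN <- mean(dN[ok]); m_dS <- mean(dS[ok])
  list(mean_dN = m_dN, mean_dS = m_dS,
       overall_omega = if (m_dS > 0) m_dN / m_dS else NA_real_,
       n_pairs = sum(ok), dN = dN, dS = dS)
}

#' Sliding-window divergence profile
#'
#' Means of JC nucleotide distance K, NG86 dN and the per-pair dN/dS ratio
#' in codon-aligned windows over a set of sequence pairs. Windows where a
#' pair's dS is 0 or saturated contribute no ratio for that pair; a window
#' where no pair has a defined ratio reports \code{NA}, never 0.
#'
#' @param aln a \code{codon_alignment}.
#' @param pairs 2-column matrix or data.frame of sequence ids.
#' @param window_nt window size in nucleotides (multiple of 3), default 30.
#' @param step_nt step in nucleotides (multiple of 3), default 9.
#' @return data.frame of class \code{window_profile}: \code{start_1based},
#'   \code{end_1based}, \code{K}, \code{dN}, \code{dN_dS}. Window count is
#'   \code{floor((L - window)/step) + 1}.
#' @export
sliding_window <- function(aln, pairs, window_nt = 30L, step_nt = 9L) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1L) stop("empty pair set")
  if (window_nt %% 3L != 0L || step_nt %% 3L != 0L)
    stop("window_nt and step_nt must be multiples of 3")
  if (window_nt > aln$length_nt) stop("window larger than alignment")
  i1 <- match(pairs[, 1], aln$names); i2 <- match(pairs[, 2], aln$names)
  if (anyNA(i1) || anyNA(i2)) stop("pair ids not in alignment")
  starts0 <- seq(0L, aln$length_nt - window_nt, by = step_nt)
  out <- data.frame(start_1based = starts0 + 1L,
                    end_1based = starts0 + window_nt,
                    K = NA_real_, dN = NA_real_, dN_dS = NA_real_)
  for (w in seq_along(starts0)) {
    Ks <- dNs <- ratio <- numeric(0)
    for (p in seq_len(nrow(pairs))) {
      sa <- substr(aln$sequences[i1[p]], starts0[w] + 1L, starts0[w] + window_nt)
      sb <- substr(aln$sequences[i2[p]], starts0[w] + 1L, starts0[w] + window_nt)
      K <- tryCatch(jc_distance(sa, sb), error = function(e) NA_real_)
      d <- tryCatch(ng86_pair(sa, sb), error = function(e) NULL)
      Ks <- c(Ks, K)
      if (!is.null(d)) {
        dNs <- c(dNs, d$dN)
        if (is.finite(d$omega)) ratio <- c(ratio, d$omega)
      }
    }
    out$K[w] <- if (any(is.finite(Ks))) mean(Ks, na.rm = TRUE) else NA_real_
    out$dN[w] <- if (any(is.finite(dNs))) mean(dNs, na.rm = TRUE) else NA_real_
    out$dN_dS[w] <- if (length(ratio)) mean(ratio) else NA_real_
  }
  class(out) <- c("window_profile", "data.frame")
  attr(out, "window_nt") <- window_nt
  attr(out, "step_nt") <- step_nt
  out
}

#' Write a window profile as TSV
#' @param profile a \code{window_profile}.
#' @param path output path.
#' @return the profile, invisibly.
#' @export
write_window_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(profile)
}
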