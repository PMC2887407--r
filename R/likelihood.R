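# Felsenstein pruning over codon site patterns, with per-pattern scaling.
# The engine precompiles the alignment into unique site patterns with
# multiplicity weights and the tree into a postorder edge list, so repeated
# likelihood evaluations during optimisation only redo the numeric work.

#' @noRd
new_lnl_engine <- function(aln, tree) {
  phy <- tree$phy
  if (!all(phy$tip.label %in% aln$names))
    stop("tree taxa missing from alignment: ",
         paste(setdiff(phy$tip.label, aln$names), collapse = ", "))
  states <- codon_state_matrix(aln)[, phy$tip.label, drop = FALSE]
  key <- apply(states, 1, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- states[first, , drop = FALSE]
  w <- as.numeric(table(key)[key[first]])
  pat_of_site <- match(key, key[first])

  idx <- ape::reorder.phylo(phy, "postorder", index.only = TRUE)
  edge <- phy$edge[idx, , drop = FALSE]
  edge_class <- tree$edge_class[idx]
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  root <- setdiff(edge[, 1], edge[, 2])[1]
  # internal nodes in postorder: parents in first-completion order
  internal_po <- unique(edge[, 1])
  edges_of <- lapply(seq_len(n_node), function(nd) which(edge[, 1] == nd))

  npat <- nrow(pat)
  pat0 <- pat
  pat0[is.na(pat0)] <- 0L
  list(phy = phy, edge = edge, edge_len = phy$edge.length[idx],
       edge_class = edge_class, class_levels = sort(unique(edge_class)),
       root = root, internal_po = internal_po, edges_of = edges_of,
       n_tip = n_tip, n_node = n_node, npat = npat, w = w,
       pat = pat, pat0 = pat0, pat_of_site = pat_of_site,
       perm = idx)
}

# Contribution of a child node through its branch: P %*% D for an internal
# child; for a tip the conditional likelihood is an indicator, so the
# product is just column selection from P (missing codons give 1).
#' @noRd
child_G <- function(eng, P, node, D) {
  if (node > eng$n_tip) return(P %*% D[[node]])
  s <- eng$pat[, node]
  ok <- !is.na(s)
  if (all(ok)) return(P[, s, drop = FALSE])
  G <- matrix(1, 61L, eng$npat)
  G[, ok] <- P[, s[ok]]
  G
}

# Per-edge transition matrices for one site class: list over postorder edges.
# decomp_cache is an environment keyed by omega value.
#' @noRd
class_pmats <- function(eng, model, omegas_by_edge, edge_len,
                        decomp_cache = new.env(parent = emptyenv())) {
  pi <- unname(model$codon_freqs)
  lapply(seq_along(edge_len), function(e) {
    t <- edge_len[e]
    if (t == 0) return(diag(61L))
    key <- sprintf("%.15g_%.15g", model$kappa, omegas_by_edge[e])
    dec <- decomp_cache[[key]]
    if (is.null(dec)) {
      dec <- decompose_generator(build_rate_matrix(model, omegas_by_edge[e]), pi)
      decomp_cache[[key]] <- dec
    }
    pmat_from_decomp(dec, t)
  })
}

# Combine per-class per-pattern log-likelihoods with mixture weights.
#' @noRd
mix_loglik <- function(logL_k, weights, w_pat) {
  if (nrow(logL_k) == 1L) return(sum(w_pat * logL_k[1, ]))
  m <- apply(logL_k, 2, max)
  ll <- m + log(colSums(weights * exp(sweep(logL_k, 2, m))))
  sum(w_pat * ll)
}

# Full evaluation: kappa/pi in `model`, site-class weights and K x n_class
# omega matrix from a compiled spec layout.
#' @noRd
eval_loglik <- function(eng, model, weights, omega_kc, edge_len = eng$edge_len,
                        per_class = FALSE,
                        decomp_cache = new.env(parent = emptyenv())) {
  K <- length(weights)
  cls <- match(eng$edge_class, colnames(omega_kc))
  logL_k <- matrix(0, K, eng$npat)
  pi <- unname(model$codon_freqs)
  for (k in seq_len(K)) {
    Plist <- class_pmats(eng, model, omega_kc[k, cls], edge_len, decomp_cache)
    logL_k[k, ] <- cpp_prune_loglik(eng$edge, eng$n_tip, eng$n_node, Plist,
                                    eng$pat0, pi, eng$root)
  }
  lnL <- mix_loglik(logL_k, weights, eng$w)
  if (per_class) list(lnL = lnL, logL_k = logL_k) else lnL
}

#' Log-likelihood of a codon alignment under a specified model
#'
#' Felsenstein pruning over compressed codon site patterns. Site-mixture
#' models sum class likelihoods weighted by the class proportions at each
#' site; branch models use each branch's class omega in that branch's
#' transition matrix; branch-site models combine both. Columns that are
#' entirely gaps contribute log 1 = 0. A degenerate single-taxon tree gives
#' the stationary log-likelihood \eqn{\sum_h \log \pi(codon_h)}.
#'
#' @param aln a \code{codon_alignment}.
#' @param tree a \code{labeled_tree} over the alignment's taxa (ignored for
#'   a single-sequence alignment when NULL).
#' @param spec a \code{branch_model_spec} or \code{site_model_spec}.
#' @param params named list of natural-scale parameter values: \code{kappa}
#'   plus the spec's parameters (see [branch_model_spec()] and
#'   [site_model_spec()]).
#' @param model optional \code{codon_model} supplying kappa and codon
#'   frequencies; if NULL, built from \code{params$kappa} and F3x4
#'   frequencies of the alignment.
#' @return the log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(aln, tree, spec, params, model = NULL) {
  if (is.null(model)) {
    model <- codon_model(kappa = params$kappa %||% 2,
                         codon_freqs = f3x4_frequencies(aln),
                         freq_mode = "F3x4")
  } else if (!is.null(params$kappa)) {
    model$kappa <- params$kappa
  }
  if (is.null(tree) || length(aln$names) == 1L) {
    s <- codon_state_matrix(aln)[, 1]
    return(sum(log(unname(model$codon_freqs)[s[!is.na(s)]])))
  }
  eng <- new_lnl_engine(aln, tree)
  layout <- compile_spec(spec, eng$class_levels)
  rs <- layout$resolve(params)
  eval_loglik(eng, model, rs$weights, rs$omega_kc)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
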