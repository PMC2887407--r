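# Maximum-likelihood fitting of codon models: multi-start quasi-Newton over
# the model's omega/mixture parameters (and kappa), with branch lengths
# either fixed or refined by cycles of single-branch Brent optimisation
# using cached edge partials.

#' @noRd
to_theta <- function(v, transform) {
  switch(transform,
         log = log(v),
         logit = stats::qlogis(v),
         log_ge1 = log(v - 1 + 1e-6))
}

#' @noRd
from_theta <- function(th, transform) {
  switch(transform,
         log = exp(th),
         logit = stats::plogis(th),
         log_ge1 = 1 - 1e-6 + exp(th))
}

#' Fit a codon model by maximum likelihood
#'
#' Maximises the [log_likelihood()] of a branch, site or branch-site model.
#' Free omega-type parameters are optimised on a log (or logit, when bounded
#' in (0,1)) scale within the box \eqn{[10^{-6}, 999]}; class proportions
#' through stick-breaking logits; beta shapes on a log scale in
#' \eqn{[0.005, 99]}. Optimisation is multi-start (the omega-type parameters
#' are started at each value in \code{starts}) and deterministic: no
#' randomness is involved.
#'
#' Branch lengths are taken from the tree when
#' \code{branch_lengths = "fixed"} (the customary workflow estimates them
#' once under M0 and fixes them for every other model); with
#' \code{"estimate"} they are initialised from pairwise distances (or the
#' tree's own lengths), scaled jointly, and then refined by per-branch
#' Brent cycles alternated with re-optimisation of the global parameters.
#'
#' An omega estimate at or above 990 is reported in
#' \code{unbounded_params} and rendered as infinite in tables.
#'
#' @param aln a \code{codon_alignment}.
#' @param tree a \code{labeled_tree}.
#' @param spec a \code{branch_model_spec} or \code{site_model_spec}.
#' @param freqs \code{"F3x4"} (default), \code{"equal"},
#'   \code{"empirical"}, or a numeric vector of 61 codon frequencies.
#' @param kappa NULL to estimate jointly (default), or a fixed value.
#' @param branch_lengths \code{"estimate"} or \code{"fixed"}.
#' @param starts numeric vector of omega start values (default
#'   \code{c(0.05, 0.5, 2)}).
#' @param control list: \code{outer_max} (default 8 rounds of
#'   sweep+reoptimise), \code{outer_tol} (1e-6 on lnL), \code{sweeps} per
#'   round (1), \code{optim_maxit} (200).
#' @return object of class \code{codon_fit}: \code{lnL}, \code{estimates}
#'   (kappa, the spec's natural parameters, site-class \code{proportions},
#'   the resolved \code{omega} per site class x branch class, and
#'   \code{branch_lengths}), \code{n_params} (the model's omega/mixture
#'   parameter count, the "p" of customary report tables),
#'   \code{n_free_total} (including kappa and branch lengths when
#'   estimated), \code{converged}, \code{unbounded_params}, \code{spec},
#'   \code{model}, \code{tree} (with fitted lengths), \code{aln}.
#' @export
fit_codon_model <- function(aln, tree, spec,
                            freqs = "F3x4", kappa = NULL,
                            branch_lengths = c("estimate", "fixed"),
                            starts = c(0.05, 0.5, 2),
                            control = list()) {
  branch_lengths <- match.arg(branch_lengths)
  ctl <- utils::modifyList(list(outer_max = 8L, outer_tol = 1e-5,
                                sweeps = 1L, optim_maxit = 200L,
                                ndeps = 1e-5), control)
  pi <- if (is.numeric(freqs)) freqs
        else switch(freqs,
                    F3x4 = f3x4_frequencies(aln),
                    equal = equal_frequencies(),
                    empirical = empirical_codon_frequencies(aln))
  freq_mode <- if (is.numeric(freqs)) "custom" else freqs
  est_kappa <- is.null(kappa)
  kappa0 <- kappa %||% 2

  eng <- new_lnl_engine(aln, tree)
  layout <- compile_spec(spec, eng$class_levels)
  est_bls <- branch_lengths == "estimate"
  t_cur <- init_branch_lengths(aln, eng, est_bls)

  par <- layout$par
  # theta vector: [log kappa]? + spec params + [log bl-scale]?
  mk_theta <- function(om_start, with_scale) {
    init <- vapply(seq_len(nrow(par)), function(i) {
      switch(par$role[i],
             omega = if (par$transform[i] == "logit") min(om_start, 0.9)
               else if (par$transform[i] == "log_ge1") 1 + om_start
               else om_start,
             prop = 0.8,
             beta = if (par$name[i] == "p") 0.5 else 1.5)
    }, numeric(1))
    th <- mapply(to_theta, init, par$transform)
    if (est_kappa) th <- c(log(kappa0), th)
    if (with_scale) th <- c(th, 0)
    th
  }
  bounds <- function(with_scale) {
    lo <- mapply(to_theta, par$lower, par$transform)
    hi <- mapply(to_theta, par$upper, par$transform)
    if (est_kappa) { lo <- c(log(0.01), lo); hi <- c(log(100), hi) }
    if (with_scale) { lo <- c(lo, log(1e-3)); hi <- c(hi, log(1e3)) }
    list(lo = lo, hi = hi)
  }
  unpack <- function(th, with_scale) {
    i <- 0L
    k <- if (est_kappa) { i <- 1L; exp(th[1]) } else kappa0
    np <- nrow(par)
    nat <- mapply(from_theta, th[i + seq_len(np)], par$transform,
                  SIMPLIFY = TRUE)
    params <- stats::setNames(as.list(nat), par$name)
    sc <- if (with_scale) exp(th[length(th)]) else 1
    list(kappa = k, params = params, scale = sc)
  }
  fit_cache <- new.env(parent = emptyenv())
  objective <- function(th, with_scale) {
    u <- unpack(th, with_scale)
    model <- codon_model(u$kappa, pi, freq_mode)
    rs <- layout$resolve(u$params)
    val <- tryCatch(
      eval_loglik(eng, model, rs$weights, rs$omega_kc,
                  edge_len = t_cur * u$scale, decomp_cache = fit_cache),
      error = function(e) -Inf)
    if (!is.finite(val)) 1e10 else -val
  }

  run_optim <- function(th0, with_scale) {
    b <- bounds(with_scale)
    stats::optim(th0, objective, method = "L-BFGS-B",
                 lower = b$lo, upper = b$hi, with_scale = with_scale,
                 control = list(maxit = ctl$optim_maxit,
                                ndeps = rep(ctl$ndeps, length(th0)),
                                factr = 1e5))
  }

  # stage A: multi-start over global parameters (+ overall scale if branch
  # lengths are being estimated). With fixed branch lengths every start is
  # refined in full (the surfaces of the mixture models can be multimodal);
  # when branch lengths are estimated the starts are scanned and the best
  # one refined, the expensive part of the fit being the branch-length
  # cycles that follow.
  best <- NULL
  if (est_bls) {
    cands <- lapply(starts, function(s) mk_theta(s, TRUE))
    vals <- vapply(cands, objective, numeric(1), with_scale = TRUE)
    best <- run_optim(cands[[which.min(vals)]], TRUE)
  } else {
    for (s in starts) {
      res <- run_optim(mk_theta(s, FALSE), FALSE)
      if (is.null(best) || res$value < best$value) best <- res
    }
  }
  conv <- best$convergence == 0
  if (est_bls) {
    u <- unpack(best$par, TRUE)
    t_cur <- t_cur * u$scale
    th <- best$par[-length(best$par)]
    lnL <- -best$value
    for (round in seq_len(ctl$outer_max)) {
      u <- unpack(th, FALSE)
      model <- codon_model(u$kappa, pi, freq_mode)
      rs <- layout$resolve(u$params)
      for (sw in seq_len(ctl$sweeps))
        t_cur <- branch_sweep(eng, model, rs$weights, rs$omega_kc, t_cur,
                              decomp_cache = fit_cache)
      res <- run_optim(th, FALSE)
      th <- res$par
      new_lnL <- -res$value
      if (abs(new_lnL - lnL) < ctl$outer_tol) { lnL <- new_lnL; break }
      lnL <- new_lnL
      if (round == ctl$outer_max) conv <- FALSE
    }
    best <- list(par = th, value = -lnL, convergence = res$convergence)
  }

  u <- unpack(best$par, FALSE)
  model <- codon_model(u$kappa, pi, freq_mode)
  rs <- layout$resolve(u$params)
  lnL <- eval_loglik(eng, model, rs$weights, rs$omega_kc, edge_len = t_cur)

  # map fitted branch lengths back to the tree's original edge order
  phy <- tree$phy
  phy$edge.length[eng$perm] <- t_cur
  fitted_tree <- labeled_tree(phy, tree$edge_class)

  omegas <- unlist(u$params[par$name[par$role == "omega"]])
  unbounded <- names(omegas)[omegas >= 990]
  n_free_total <- layout$n_omega_params +
    (spec_extra_params(layout)) + est_kappa + if (est_bls) length(t_cur) else 0L

  structure(list(
    lnL = lnL,
    estimates = list(kappa = u$kappa, params = u$params,
                     proportions = rs$weights, omega = rs$omega_kc,
                     branch_lengths = t_cur),
    n_params = layout$n_omega_params,
    n_free_total = n_free_total,
    converged = conv,
    unbounded_params = unbounded,
    spec = spec, model = model, tree = fitted_tree, aln = aln,
    weights = rs$weights, omega_kc = rs$omega_kc,
    flag_classes = layout$flag_classes
  ), class = "codon_fit")
}

# n_omega_params already counts every free spec parameter (props, betas and
# omegas alike), so no extras beyond it.
#' @noRd
spec_extra_params <- function(layout) 0L

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon model fit:", x$spec$name, "\n")
  cat("  lnL =", format(x$lnL, nsmall = 2), " p =", x$n_params,
      " converged:", x$converged, "\n")
  om <- x$omega_kc
  if (nrow(om) == 1L) {
    cat("  omega by branch class:\n")
    print(round(om[1, ], 4))
  } else {
    cat("  site classes:", paste(round(x$weights, 3), collapse = ", "), "\n")
  }
  if (length(x$unbounded_params))
    cat("  at upper bound (reported as Inf):",
        paste(x$unbounded_params, collapse = ", "), "\n")
  invisible(x)
}

# initial branch lengths: the tree's own lengths when positive, otherwise a
# least-squares fit (phangorn::nnls.tree) to pairwise JC distances converted
# to codon units.
#' @noRd
init_branch_lengths <- function(aln, eng, est_bls) {
  t0 <- eng$edge_len
  if (!est_bls) return(t0)
  if (all(t0 > 1e-9)) return(t0)
  n <- length(eng$phy$tip.label)
  D <- matrix(0, n, n, dimnames = list(eng$phy$tip.label, eng$phy$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- tryCatch(jc_distance(
      aln$sequences[match(eng$phy$tip.label[i], aln$names)],
      aln$sequences[match(eng$phy$tip.label[j], aln$names)]),
      error = function(e) NA_real_)
    if (!is.finite(d)) d <- 2
    D[i, j] <- D[j, i] <- 3 * d  # nucleotide -> codon units, roughly
  }
  ls_tree <- tryCatch(phangorn::nnls.tree(as.dist(D), eng$phy,
                                          method = "unrooted"),
                      error = function(e) NULL)
  if (is.null(ls_tree)) return(pmax(t0, 0.05))
  m <- match(paste(eng$phy$edge[, 1], eng$phy$edge[, 2]),
             paste(ls_tree$edge[, 1], ls_tree$edge[, 2]))
  if (anyNA(m)) return(pmax(t0, 0.05))
  out <- pmax(ls_tree$edge.length[m], 1e-4)  # original edge order
  out[eng$perm]
}

# One cycle of per-branch Brent optimisation. For each edge the downward and
# upward partials are recomputed under the current lengths, then the edge's
# length is optimised with everything else held fixed.
#' @noRd
branch_sweep <- function(eng, model, weights, omega_kc, t_cur,
                         t_max = 20,
                         decomp_cache = new.env(parent = emptyenv())) {
  K <- length(weights)
  cls <- match(eng$edge_class, colnames(omega_kc))
  pi <- unname(model$codon_freqs)
  get_dec <- function(om) {
    key <- sprintf("%.15g_%.15g", model$kappa, om)
    d <- decomp_cache[[key]]
    if (is.null(d)) {
      d <- decompose_generator(build_rate_matrix(model, om), pi)
      decomp_cache[[key]] <- d
    }
    d
  }
  for (e in seq_len(nrow(eng$edge))) {
    v <- eng$edge[e, 2]
    parts <- lapply(seq_len(K), function(k) {
      Plist <- class_pmats(eng, model, omega_kc[k, cls], t_cur, decomp_cache)
      ep <- cpp_edge_partials(eng$edge, eng$n_tip, eng$n_node, Plist,
                              eng$pat0, pi, eng$root, e)
      ep$dec <- get_dec(omega_kc[k, cls[e]])
      ep
    })
    flow <- function(P, pt) {
      if (is.null(pt$D)) child_G(eng, P, v, NULL) else P %*% pt$D
    }
    f <- function(t) {
      logL_k <- matrix(0, K, eng$npat)
      for (k in seq_len(K)) {
        pt <- parts[[k]]
        P <- if (t == 0) diag(61L) else pmat_from_decomp(pt$dec, t)
        a <- pmax(colSums(pt$U * flow(P, pt)), 1e-300)
        logL_k[k, ] <- log(a) + pt$uls + pt$dls
      }
      -mix_loglik(logL_k, weights, eng$w)
    }
    opt <- stats::optimize(f, c(0, max(t_max, 4 * t_cur[e])), tol = 1e-7)
    if (opt$objective <= f(t_cur[e])) t_cur[e] <- opt$minimum
  }
  t_cur
}

#' Posterior site classification of a fitted mixture model
#'
#' Naive empirical Bayes: the posterior probability of site class k at site
#' h is \eqn{p_k L_h(k) / \sum_j p_j L_h(j)} with the mixture proportions
#' and class likelihoods evaluated at the maximum-likelihood estimates.
#' Sites whose summed posterior over classes with omega > 1 (on foreground
#' branches, for branch-site models) reaches \code{threshold} are flagged,
#' with the amino acid of the first sequence as reference residue. The
#' flagged set is empty whenever no class has omega > 1.
#'
#' @param fit a \code{codon_fit} of a site or branch-site mixture model.
#' @param threshold posterior probability cutoff for flagging (default 0.95).
#' @return list with \code{posterior} (sites x classes matrix),
#'   \code{p_positive} (per-site summed posterior of positive classes),
#'   \code{flagged_sites} (data.frame site, residue, posterior),
#'   \code{method = "NEB"}.
#' @export
site_posteriors <- function(fit, threshold = 0.95) {
  if (length(fit$weights) < 2L)
    stop("site posteriors require a site-mixture or branch-site model")
  eng <- new_lnl_engine(fit$aln, fit$tree)
  res <- eval_loglik(eng, fit$model, fit$weights, fit$omega_kc,
                     per_class = TRUE)
  lw <- log(fit$weights)
  post_pat <- apply(res$logL_k, 2, function(l) {
    l <- l + lw
    l <- l - max(l)
    p <- exp(l)
    p / sum(p)
  })
  post <- t(post_pat)[eng$pat_of_site, , drop = FALSE]
  colnames(post) <- paste0("class", seq_along(fit$weights))
  # positive classes: omega > 1 somewhere (foreground included); for
  # branch-site specs the compiled layout marks the switching classes, of
  # which only those with foreground omega > 1 count.
  fg_max <- apply(fit$omega_kc, 1, max)
  pos <- which(fg_max > 1 + 1e-9)
  if (!is.null(fit$flag_classes)) pos <- intersect(fit$flag_classes, pos)
  p_positive <- if (length(pos)) rowSums(post[, pos, drop = FALSE])
                else rep(0, nrow(post))
  aa <- the_code()$codon_to_aa
  ref <- aa[codon_matrix(fit$aln)[, 1]]
  flagged <- which(p_positive >= threshold)
  list(posterior = post,
       p_positive = p_positive,
       flagged_sites = data.frame(site = flagged,
                                  residue = unname(ref[flagged]),
                                  posterior = p_positive[flagged]),
       method = "NEB")
}
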