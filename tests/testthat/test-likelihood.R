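test_that("rate matrix has generator structure, reversibility and limits", {
  set.seed(13)
  for (rep in 1:5) {
    kappa <- runif(1, 0.5, 5)
    omega <- runif(1, 0.01, 3)
    pi <- as.numeric(rdirichlet1(61))
    m <- codon_model(kappa, pi / sum(pi))
    Q <- build_rate_matrix(m, omega)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    piv <- unname(m$codon_freqs)
    # detailed balance pi_i q_ij = pi_j q_ji
    expect_lt(max(abs(piv * Q - t(piv * Q))), 1e-12)
    # unit expected substitution rate
    expect_equal(-sum(piv * diag(Q)), 1, tolerance = 1e-12)
  }
  # neutral equal-frequency limit: all allowed single-step rates equal
  m1 <- codon_model(1, equal_frequencies())
  Q1 <- build_rate_matrix(m1, 1)
  off <- Q1[row(Q1) != col(Q1)]
  expect_equal(sort(unique(round(off[off > 0], 12))),
               unique(round(off[off > 0], 12))[1])
  expect_error(build_rate_matrix(m1, -0.5), ">= 0")
})

test_that("transition probabilities behave like a Markov semigroup", {
  m <- codon_model(2.5, f3x4_frequencies(random_codon_alignment(4, 200, 3)))
  Q <- build_rate_matrix(m, 0.2)
  expect_equal(transition_probabilities(Q, 0, m), diag(61L))
  P1 <- transition_probabilities(Q, 0.37, m)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  expect_true(all(P1 >= 0))
  # Chapman-Kolmogorov
  P2 <- transition_probabilities(Q, 0.58, m)
  P12 <- transition_probabilities(Q, 0.95, m)
  expect_lt(max(abs(P1 %*% P2 - P12)), 1e-8)
  # long-time stationarity
  Pinf <- transition_probabilities(Q, 100, m)
  expect_lt(max(abs(sweep(Pinf, 2, unname(m$codon_freqs)))), 1e-6)
  expect_error(transition_probabilities(Q, NA), "finite")
})

test_that("pruning equals brute-force summation over internal states", {
  set.seed(41)
  sense <- genetic_code()$sense_codons
  phy <- ape::read.tree(text = "((A:0.2,B:0.35):0.15,C:0.4);")
  tr <- labeled_tree(phy)
  for (rep in 1:5) {
    seqs <- replicate(3, paste(sample(sense, 5, TRUE), collapse = ""))
    aln <- codon_alignment(c("A", "B", "C"), seqs)
    kappa <- runif(1, 1, 4); omega <- runif(1, 0.05, 2)
    pi <- f3x4_frequencies(aln)
    m <- codon_model(kappa, pi)
    got <- log_likelihood(aln, tr, branch_model_spec("M0"),
                          params = list(kappa = kappa, w = omega), model = m)
    want <- oracle_loglik_3taxa(aln, 0.2, 0.35, 0.15, 0.4, kappa, omega, pi)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to rerooting, site order and taxon order", {
  sim <- simulate_codon_alignment(simulation_spec(
    make_duplication_tree(3, 2), omega = 0.2, n_codons = 60, seed = 17))
  aln <- sim$alignment
  tree <- sim$truth$tree
  spec <- branch_model_spec("M0")
  pars <- list(kappa = 2, w = 0.2)
  m <- codon_model(2, f3x4_frequencies(aln))
  base <- log_likelihood(aln, tree, spec, pars, model = m)

  # reroot (reversible model: pulley principle)
  for (og in c("g1_sp1", "g5_sp2")) {
    re <- ape::root(ape::unroot(tree$phy), outgroup = og,
                    resolve.root = TRUE)
    expect_equal(log_likelihood(aln, labeled_tree(re), spec, pars,
                                model = m),
                 base, tolerance = 1e-8)
  }

  # site order
  set.seed(3)
  shuf <- sample(aln$n_codons)
  resh <- vapply(aln$sequences, function(s)
    paste(substring(s, shuf * 3 - 2, shuf * 3), collapse = ""),
    character(1))
  expect_equal(log_likelihood(codon_alignment(aln$names, unname(resh)),
                              tree, spec, pars, model = m),
               base, tolerance = 1e-9)

  # taxon order in the alignment
  ord <- rev(seq_along(aln$names))
  expect_equal(log_likelihood(codon_alignment(aln$names[ord],
                                              aln$sequences[ord]),
                              tree, spec, pars, model = m),
               base, tolerance = 1e-9)
})

test_that("degenerate inputs: single taxon, all-gap columns, zero branches", {
  aln1 <- codon_alignment("A", "ATGTTTGGA")
  m <- codon_model(2, equal_frequencies())
  expect_equal(log_likelihood(aln1, NULL, branch_model_spec("M0"),
                              params = list(kappa = 2, w = 1), model = m),
               3 * log(1 / 61), tolerance = 1e-12)

  # an all-gap column contributes log 1 = 0
  tr <- labeled_tree(ape::read.tree(text = "(a:0.1,b:0.1);"))
  a0 <- codon_alignment(c("a", "b"), c("TTTAAA", "TTCAAA"))
  a1 <- codon_alignment(c("a", "b"), c("TTTAAA---", "TTCAAA---"))
  p <- list(kappa = 2, w = 0.5)
  expect_equal(log_likelihood(a0, tr, branch_model_spec("M0"), p, model = m),
               log_likelihood(a1, tr, branch_model_spec("M0"), p, model = m),
               tolerance = 1e-12)

  # zero-length branches give P(0) = I exactly
  phy0 <- ape::read.tree(text = "(a:0,b:0);")
  ll <- log_likelihood(a0, labeled_tree(phy0), branch_model_spec("M0"), p,
                       model = m)
  expect_true(is.finite(ll))
})

test_that("site mixtures average class likelihoods with the proportions", {
  sim <- simulate_codon_alignment(simulation_spec(
    make_duplication_tree(2, 2), omega = 0.3, n_codons = 40, seed = 19))
  aln <- sim$alignment
  tree <- sim$truth$tree
  m <- codon_model(2, f3x4_frequencies(aln))
  # a two-class mixture with identical omegas equals the one-class model
  ll_mix <- log_likelihood(aln, tree, site_model_spec("M3", n_classes = 2),
                           params = list(p0 = 0.3, w0 = 0.3, w1 = 0.3),
                           model = m)
  ll_one <- log_likelihood(aln, tree, branch_model_spec("M0"),
                           params = list(w = 0.3), model = m)
  expect_equal(ll_mix, ll_one, tolerance = 1e-9)
})
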