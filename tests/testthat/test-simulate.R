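test_that("simulation is deterministic and FASTA-byte stable", {
  spec <- preset_simulation("duplication_m3r", n_codons = 87, seed = 33)
  a <- simulate_codon_alignment(spec)
  b <- simulate_codon_alignment(spec)
  expect_identical(a$alignment, b$alignment)
  expect_identical(a$truth$site_class, b$truth$site_class)
  f1 <- tempfile(); f2 <- tempfile()
  write_codon_fasta(a$alignment, f1)
  write_codon_fasta(b$alignment, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a different seed changes the data
  c2 <- simulate_codon_alignment(
    preset_simulation("duplication_m3r", n_codons = 87, seed = 34))
  expect_false(identical(a$alignment$sequences, c2$alignment$sequences))
})

test_that("zero-length trees copy the root draw to every tip", {
  phy <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  sim <- simulate_codon_alignment(simulation_spec(
    labeled_tree(phy), omega = 0.5, n_codons = 50, seed = 3))
  expect_equal(length(unique(sim$alignment$sequences)), 1L)
})

test_that("substitution counts match the scaled-generator expectation", {
  # two taxa, t = 0.5 each side, omega = kappa = 1, equal frequencies:
  # expected 1.0 substitution event per codon along the path; observed
  # state changes are fewer (multiple hits), so compare against the
  # transition-matrix prediction of the change probability.
  tr <- labeled_tree(ape::read.tree(text = "(a:0.5,b:0.5);"))
  m <- codon_model(1, equal_frequencies())
  Q <- build_rate_matrix(m, 1)
  P <- transition_probabilities(Q, 1.0, m)  # pulley: a-to-b distance 1.0
  p_change <- 1 - sum(unname(m$codon_freqs) * diag(P))
  n <- 4000
  sim <- simulate_codon_alignment(simulation_spec(
    tr, kappa = 1, codon_freqs = equal_frequencies(), omega = 1,
    n_codons = n, seed = 9))
  ca <- split_codons_chr(sim$alignment$sequences[1])
  cb <- split_codons_chr(sim$alignment$sequences[2])
  obs <- mean(ca != cb)
  se <- sqrt(p_change * (1 - p_change) / n)
  expect_lt(abs(obs - p_change), 3 * se)
})

test_that("long-branch simulation is stationary at the model frequencies", {
  pi <- biased_frequencies(0.7)
  tr <- labeled_tree(ape::read.tree(text = "(a:0.01,b:6);"))
  ok <- 0L
  for (s in 1:20) {
    sim <- simulate_codon_alignment(simulation_spec(
      tr, omega = 0.5, codon_freqs = pi, n_codons = 3000, seed = 200 + s))
    cods <- split_codons_chr(
      sim$alignment$sequences[match("b", sim$alignment$names)])
    obs <- table(factor(cods, levels = genetic_code()$sense_codons))
    gof <- suppressWarnings(stats::chisq.test(obs, p = unname(pi)))
    if (gof$p.value > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("duplication tree is shaped and labelled consistently", {
  tr <- make_duplication_tree(2, 2)
  expect_equal(length(tr$phy$tip.label), 5L)
  expect_setequal(unique(tr$edge_class),
                  c("pre", "stem_g1", "stem_g5", "g1", "g5"))
  # exactly one stem branch per paralog clade
  expect_equal(sum(tr$edge_class == "stem_g1"), 1L)
  expect_equal(sum(tr$edge_class == "stem_g5"), 1L)

  # every path from a paralog tip to the root crosses its own stem once,
  # and only pre branches above the duplication node
  tr2 <- make_duplication_tree(4, 3)
  phy <- tr2$phy
  for (tip in seq_along(phy$tip.label)) {
    node <- tip
    classes <- character(0)
    repeat {
      e <- which(phy$edge[, 2] == node)
      if (length(e) == 0) break
      classes <- c(classes, tr2$edge_class[e])
      node <- phy$edge[e, 1]
    }
    lab <- phy$tip.label[tip]
    if (grepl("^g1_", lab)) {
      expect_equal(sum(classes == "stem_g1"), 1L)
      expect_true(all(classes %in% c("g1", "stem_g1", "pre")))
    } else if (grepl("^g5_", lab)) {
      expect_equal(sum(classes == "stem_g5"), 1L)
      expect_true(all(classes %in% c("g5", "stem_g5", "pre")))
    } else {
      expect_true(all(classes == "pre"))
    }
  }
})

test_that("labelled trees round-trip through Newick + label TSV", {
  tr <- make_duplication_tree(3, 2)
  nwk <- tempfile(fileext = ".nwk")
  lab <- tempfile(fileext = ".tsv")
  write_labeled_tree(tr, nwk, lab)
  back <- read_labeled_tree(nwk, lab)
  expect_equal(back$phy$tip.label, tr$phy$tip.label)
  expect_equal(back$phy$edge, tr$phy$edge)
  expect_equal(back$phy$edge.length, tr$phy$edge.length, tolerance = 1e-9)
  expect_identical(back$edge_class, tr$edge_class)
})

test_that("inline # tags in Newick label the subtending branches", {
  txt <- "((a#fast:0.1,b:0.2)#fast:0.05,c:0.3);"
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  tr <- read_labeled_tree(f)
  tagged_children <- paralogsel:::node_id(tr$phy, tr$phy$edge[, 2])[
    tr$edge_class == "fast"]
  expect_setequal(tagged_children, c("a", "node5"))
  expect_equal(sum(tr$edge_class == "all"), 2L)
})

test_that("biased frequencies hit their GC3 target and its limits fail", {
  expect_error(biased_frequencies(0), "between 0 and 1")
  expect_error(biased_frequencies(1), "between 0 and 1")
  # realised GC3 of a long stationary draw
  spec <- simulation_spec(make_duplication_tree(2, 2), omega = 0.5,
                          codon_freqs = biased_frequencies(0.759),
                          n_codons = 10000, seed = 55)
  aln <- simulate_codon_alignment(spec)$alignment
  expect_equal(mean(gc_content(aln)$gc3), 0.759, tolerance = 0.02)
  # near-uniform family at 0.5
  pi50 <- biased_frequencies(0.5)
  expect_lt(max(pi50) / min(pi50), 1.2)
})

test_that("site regimes assign classes once and inherit them", {
  spec <- preset_simulation("site_mixture", n_codons = 400, seed = 12)
  sim <- simulate_codon_alignment(spec)
  expect_equal(length(sim$truth$site_class), 400L)
  expect_setequal(unique(sim$truth$site_class), c(1L, 2L))
  # class-1 (omega = 0.05) sites should be visibly more conserved than
  # class-2 (neutral) sites across the alignment
  cm <- paralogsel:::codon_matrix(sim$alignment)
  n_states <- apply(cm, 1, function(r) length(unique(r)))
  expect_lt(mean(n_states[sim$truth$site_class == 1]),
            mean(n_states[sim$truth$site_class == 2]))
})
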