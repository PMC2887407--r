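test_that("NG86 site counts match neighbour enumeration", {
  # TTT: only TTT->TTC synonymous among the 9 neighbours
  expect_equal(ng86_sites("TTT"), c(syn = 1 / 3, nonsyn = 8 / 3))
  # Trp is a single-codon amino acid
  expect_equal(ng86_sites("TGG"), c(syn = 0, nonsyn = 3))
  expect_error(ng86_sites("TAA"), "sense")

  code <- genetic_code()
  for (cd in code$sense_codons) {
    expect_equal(unname(ng86_sites(cd)), oracle_ng86_sites(cd),
                 tolerance = 1e-12)
    # exact complementarity
    expect_equal(sum(ng86_sites(cd)), 3, tolerance = 1e-12)
  }
})

test_that("NG86 pairwise counts agree with the pathway-enumeration oracle", {
  set.seed(31)
  sense <- genetic_code()$sense_codons
  for (rep in 1:50) {
    a <- paste(sample(sense, 8, TRUE), collapse = "")
    b <- paste(sample(sense, 8, TRUE), collapse = "")
    got <- ng86_pair(a, b)
    want <- oracle_ng86_pair(a, b)
    expect_equal(got$S_sites, want$S, tolerance = 1e-12)
    expect_equal(got$N_sites, want$N, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    if (is.finite(want$dS)) expect_equal(got$dS, want$dS, tolerance = 1e-12)
    # symmetry
    rev <- ng86_pair(b, a)
    expect_equal(got$Sd, rev$Sd, tolerance = 1e-12)
    expect_equal(got$dN, rev$dN, tolerance = 1e-12)
    # site counts sum to 3 per codon
    expect_equal(got$S_sites + got$N_sites, 3 * got$n_codons,
                 tolerance = 1e-12)
  }
})

test_that("NG86 pair handles identity, sign structure and concatenation", {
  s <- "TTTAAAGGGCCCATGTGGACTGAACGA"
  d0 <- ng86_pair(s, s)
  expect_equal(d0$dN, 0)
  expect_equal(d0$dS, 0)
  expect_true(is.na(d0$omega))

  # one synonymous third-position change in 10 codons
  a <- paste(rep("TTT", 10), collapse = "")
  b <- paste(c("TTC", rep("TTT", 9)), collapse = "")
  d1 <- ng86_pair(a, b)
  expect_equal(d1$Nd, 0)
  expect_equal(d1$Sd, 1)
  expect_equal(d1$dN, 0)

  # difference counts add over concatenated alignments
  set.seed(5)
  sense <- genetic_code()$sense_codons
  x1 <- paste(sample(sense, 6, TRUE), collapse = "")
  y1 <- paste(sample(sense, 6, TRUE), collapse = "")
  x2 <- paste(sample(sense, 7, TRUE), collapse = "")
  y2 <- paste(sample(sense, 7, TRUE), collapse = "")
  dc <- ng86_pair(paste0(x1, x2), paste0(y1, y2))
  da <- ng86_pair(x1, y1); db <- ng86_pair(x2, y2)
  expect_equal(dc$Sd, da$Sd + db$Sd, tolerance = 1e-12)
  expect_equal(dc$Nd, da$Nd + db$Nd, tolerance = 1e-12)

  # gapped codons dropped pairwise
  dg <- ng86_pair("---AAA", "TTTAAA")
  expect_equal(dg$n_codons, 1L)
})

test_that("JC distance matches the closed form and is symmetric", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  expect_equal(jc_distance(a, a), 0)
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-12)
  expect_equal(jc_distance(a, b), jc_distance(b, a))
  # saturation flag
  d <- jc_distance(paste(rep("A", 20), collapse = ""),
                   paste(rep("C", 20), collapse = ""))
  expect_true(is.na(d))
  expect_true(attr(d, "saturated"))
})

test_that("NG86 omega is unbiased on neutral data at large n", {
  # omega_true = 1 under equal codon frequencies; mean over replicates
  tr <- labeled_tree(ape::read.tree(text = "(a:0.25,b:0.25);"))
  oms <- vapply(1:40, function(s) {
    aln <- simulate_codon_alignment(simulation_spec(
      tr, kappa = 1, codon_freqs = equal_frequencies(), omega = 1,
      n_codons = 2500, seed = 1000 + s))$alignment
    ng86_pair(aln$sequences[1], aln$sequences[2])$omega
  }, numeric(1))
  expect_gt(mean(oms), 0.9)
  expect_lt(mean(oms), 1.1)
})

test_that("sliding windows tile the alignment and localise divergence", {
  sim <- simulate_codon_alignment(
    preset_simulation("duplication_m3r", n_codons = 106, seed = 8))
  aln <- sim$alignment  # 318 nt
  prs <- cbind("g1_sp1", "g5_sp1")
  wp <- sliding_window(aln, prs, 30, 9)
  expect_equal(nrow(wp), floor((318 - 30) / 9) + 1)  # 33 windows
  expect_equal(wp$start_1based, seq(1, 289, by = 9))
  expect_true(all(wp$end_1based <= aln$length_nt))

  # identical pair: flat zero K and dN, ratio undefined (not zero)
  two <- codon_alignment(c("x", "y"), rep(aln$sequences[1], 2))
  wp0 <- sliding_window(two, cbind("x", "y"), 30, 9)
  expect_true(all(wp0$K == 0))
  expect_true(all(wp0$dN == 0))
  expect_true(all(is.na(wp0$dN_dS)))

  # a single divergent block elevates K only where windows overlap it
  base <- paste(rep("ATGTTTGGA", 20), collapse = "")  # 180 nt
  mut <- base
  for (pos in seq(91, 118, by = 3))  # every third site in 91..120 flipped
    substr(mut, pos, pos) <- chartr("ATGC", "GCAT", substr(base, pos, pos))
  am <- codon_alignment(c("p", "q"), c(base, mut), frame_check = FALSE)
  wb <- sliding_window(am, cbind("p", "q"), 30, 9)
  hit <- wb$end_1based >= 91 & wb$start_1based <= 120
  expect_true(all(wb$K[hit] > 0))
  expect_true(all(wb$K[!hit] == 0))

  expect_error(sliding_window(aln, prs[0, , drop = FALSE]), "empty")
  expect_error(sliding_window(aln, prs, 31, 9), "multiples of 3")
})

test_that("mean divergence reproduces printed-ratio arithmetic", {
  # overall omega = mean dN / mean dS
  expect_equal(round(0.033 / 0.155, 3), 0.213)
  expect_equal(round(0.011 / 0.131, 3), 0.084)

  aln <- codon_alignment(c("a", "b"), c("TTTAAA", "TTTAAA"))
  md <- mean_divergence(aln, c("a", "b"))
  expect_equal(md$mean_dN, 0)
  expect_true(is.na(md$overall_omega))
  expect_error(mean_divergence(aln, "a"), "at least 2")
})

test_that("NJ classification places queries in the right paralog clade", {
  sim <- simulate_codon_alignment(
    preset_simulation("duplication_m3r", n_codons = 300, seed = 21))
  aln <- sim$alignment
  g1 <- grep("^g1_", aln$names, value = TRUE)
  g5 <- grep("^g5_", aln$names, value = TRUE)
  refs <- c(stats::setNames(rep("gamma1", 4), g1[1:4]),
            stats::setNames(rep("gamma5", 4), g5[1:4]))
  queries <- c(g1[5:7], g5[5:6])
  got <- nj_classify(aln, queries, refs)
  expect_equal(unname(got),
               c(rep("gamma1", 3), rep("gamma5", 2)))

  # identical to a reference -> that label
  two <- codon_alignment(c("r1", "r2", "q"),
                         c(aln$sequences[match(g1[1], aln$names)],
                           aln$sequences[match(g5[1], aln$names)],
                           aln$sequences[match(g1[1], aln$names)]))
  expect_equal(unname(nj_classify(two, "q",
                                  c(r1 = "A", r2 = "B"))), "A")

  # swapping reference labels swaps every assignment
  refs_sw <- refs
  refs_sw[refs == "gamma1"] <- "gamma5"
  refs_sw[refs == "gamma5"] <- "gamma1"
  got_sw <- nj_classify(aln, queries, refs_sw)
  expect_equal(unname(got_sw), c(rep("gamma5", 3), rep("gamma1", 2)))
})
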