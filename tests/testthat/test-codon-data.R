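test_that("codon alignment construction validates frame and alphabet", {
  aln <- codon_alignment(c("a", "b"), c("ATGTTT", "ATGTTC"))
  expect_equal(aln$n_codons, 2L)
  expect_equal(aln$length_nt, 6L)

  # internal stop codon rejected with sequence and codon position named
  expect_error(codon_alignment(c("a", "b"), c("ATGTAA", "ATGTTC")),
               "frame error.*'a'.*codon 2")
  expect_silent(codon_alignment("a", "ATGTAA", frame_check = FALSE))

  # unequal lengths
  expect_error(codon_alignment(c("a", "b"), c("ATGTTT", "ATG")),
               "unequal")
  # ambiguity codes collapse to N
  aln2 <- codon_alignment("a", "ATRCGY", frame_check = FALSE)
  expect_equal(aln2$sequences, "ATNCGN")
  # partial-codon gap normalised to a full-codon gap, with warning
  expect_warning(aln3 <- codon_alignment("a", "A-GTTT"), "partial-codon")
  expect_equal(aln3$sequences, "---TTT")
})

test_that("FASTA write -> read round trip is exact", {
  sim <- simulate_codon_alignment(
    preset_simulation("duplication_m3r", n_codons = 87, seed = 2))
  aln <- sim$alignment
  tmp <- tempfile(fileext = ".fasta")
  write_codon_fasta(aln, tmp)
  back <- read_codon_fasta(tmp)
  expect_identical(back$names, aln$names)
  expect_identical(back$sequences, aln$sequences)
  expect_error(read_codon_fasta(tempfile()), "not found")
})

test_that("GC content excludes gaps and matches hand counts", {
  aln <- codon_alignment("s", "ATGCAT", frame_check = FALSE)
  gc <- gc_content(aln)
  expect_equal(gc$gc_total, 2 / 6)
  expect_equal(gc$gc3, 1 / 2)  # third positions G, T

  allg <- gc_content(codon_alignment("g", "GGGGGG", frame_check = FALSE))
  expect_equal(unlist(allg[, c("gc_total", "gc1", "gc2", "gc3")]),
               c(gc_total = 1, gc1 = 1, gc2 = 1, gc3 = 1))

  # all-gap sequence flagged undefined
  gpd <- gc_content(codon_alignment(c("a", "b"), c("------", "ATGTTC")))
  expect_true(gpd$undefined[1])
  expect_false(gpd$undefined[2])

  # weighted average of positional GC equals total on gap-free sequences
  aln3 <- random_codon_alignment(3, 40, seed = 9)
  gc3 <- gc_content(aln3)
  expect_equal(gc3$gc_total, (gc3$gc1 + gc3$gc2 + gc3$gc3) / 3,
               tolerance = 1e-12)
})

test_that("high-GC3 generator output is recovered by gc_content", {
  spec <- simulation_spec(make_duplication_tree(2, 2), omega = 0.1,
                          codon_freqs = biased_frequencies(0.76),
                          n_codons = 10000, seed = 4)
  aln <- simulate_codon_alignment(spec)$alignment
  expect_equal(mean(gc_content(aln)$gc3), 0.76, tolerance = 0.02)
})

test_that("parsimony-informative site count matches the brute-force rule", {
  # AACC column informative, AAAC not
  a1 <- codon_alignment(letters[1:4], c("AAA", "AAA", "CAA", "CAA"))
  expect_equal(count_informative_sites(a1), 1L)
  a2 <- codon_alignment(letters[1:4], c("AAA", "AAA", "AAA", "CAA"))
  expect_equal(count_informative_sites(a2), 0L)
  expect_error(count_informative_sites(
    codon_alignment(c("a", "b"), c("AAA", "AAA"))), "fewer than 4")

  for (seed in 1:5) {
    aln <- random_codon_alignment(6, 10, seed = seed)
    m <- do.call(rbind, strsplit(aln$sequences, ""))
    expect_equal(count_informative_sites(aln),
                 sum(apply(m, 2, oracle_informative_column)))
  }

  # invariant under sequence reordering and column (codon) permutation
  aln <- random_codon_alignment(6, 30, seed = 77)
  n0 <- count_informative_sites(aln)
  perm <- codon_alignment(rev(aln$names), rev(aln$sequences))
  expect_equal(count_informative_sites(perm), n0)
  set.seed(1)
  shuf <- sample(aln$n_codons)
  resh <- vapply(aln$sequences, function(s) {
    paste(split_cod <- substring(s, shuf * 3 - 2, shuf * 3), collapse = "")
  }, character(1))
  expect_equal(count_informative_sites(
    codon_alignment(aln$names, unname(resh))), n0)
})
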