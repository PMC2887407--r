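test_that("LRT statistics reproduce printed log-likelihood arithmetic", {
  r <- lrt(-5020.93, -5015.74, df = 1)
  expect_equal(r$stat, 10.38, tolerance = 1e-9)
  expect_lt(r$p_value, 0.01)

  r2 <- lrt(-4915.09, -4908.26, df = 2)
  expect_equal(r2$stat, 13.66, tolerance = 1e-9)

  r0 <- lrt(-100, -100, df = 1)
  expect_equal(r0$stat, 0)
  expect_equal(r0$p_value, 1)

  expect_warning(rn <- lrt(-99, -100, df = 1), "negative")
  expect_equal(rn$p_value, 1)
  expect_true(rn$negative)
  expect_error(lrt(-100, -99), "df must be given")
})

test_that("chi-square p-values match reference quantiles and decrease", {
  expect_equal(round(chi2_pvalue(4.83, 1), 3), 0.028)
  expect_equal(round(chi2_pvalue(5.77, 1), 3), 0.016)
  expect_equal(chi2_pvalue(0, 1), 1)
  expect_equal(chi2_pvalue(0, 5), 1)
  s <- seq(0.1, 20, by = 0.7)
  expect_true(all(diff(chi2_pvalue(s, 1)) < 0))
  expect_error(chi2_pvalue(1, 0), "df")
  expect_error(chi2_pvalue(-1, 1), ">= 0")
})

test_that("Tajima relative rate test counts unique differences", {
  # identical ingroups: undefined
  r0 <- tajima_rrt("AAAA", "AAAA", "AATA")
  expect_true(r0$undefined)
  expect_true(is.na(r0$ratio))

  # constructed triple with m1 = 6, m2 = 2
  o <- paste(rep("A", 20), collapse = "")
  a <- paste(c(rep("C", 6), rep("A", 14)), collapse = "")     # 6 unique in a
  b <- paste(c(rep("A", 6), rep("G", 2), rep("A", 12)), collapse = "")
  r <- tajima_rrt(a, b, o)
  expect_equal(c(r$m1, r$m2), c(6, 2))
  expect_equal(r$chi2, (6 - 2)^2 / 8)
  expect_equal(r$ratio, 3)
  expect_equal(r$p_value, chi2_pvalue(2, 1))

  # swapping a and b inverts the ratio, preserves chi2
  rs <- tajima_rrt(b, a, o)
  expect_equal(rs$ratio, 1 / 3)
  expect_equal(rs$chi2, r$chi2)

  # invariant under removal of sites where all three agree
  a2 <- substr(a, 1, 8); b2 <- substr(b, 1, 8); o2 <- substr(o, 1, 8)
  r2 <- tajima_rrt(a2, b2, o2)
  expect_equal(c(r2$m1, r2$m2, r2$chi2), c(r$m1, r$m2, r$chi2))

  # gap/N positions dropped in any of the three
  rg <- tajima_rrt(paste0("C", substr(a, 2, 20)),
                   b, paste0("-", substr(o, 2, 20)))
  expect_equal(rg$m1, 5)
})

test_that("relative rate test holds its size on equal-rate simulations", {
  tr <- labeled_tree(ape::read.tree(
    text = "((a:0.15,b:0.15):0.1,o:0.25);"))
  rej <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    aln <- simulate_codon_alignment(simulation_spec(
      tr, omega = 1, n_codons = 250, seed = 5000 + s))$alignment
    r <- tajima_rrt(aln$sequences[match("a", aln$names)],
                    aln$sequences[match("b", aln$names)],
                    aln$sequences[match("o", aln$names)])
    if (!r$undefined && r$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.02)
  expect_lte(rej / n_rep, 0.09)
})

test_that("group comparison is a Welch t-test with degenerate guards", {
  x <- c(1, 2, 3, 4); y <- c(1.5, 2.5, 3.5, 4.5)
  got <- compare_groups(x, y)
  want <- t.test(x, y)
  expect_equal(got$t_stat, unname(want$statistic))
  expect_equal(got$p_value, want$p.value)

  # swap negates t, keeps p
  sw <- compare_groups(y, x)
  expect_equal(sw$t_stat, -got$t_stat)
  expect_equal(sw$p_value, got$p_value)

  # identical constant groups: p = 1, not an error
  cg <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(cg$p_value, 1)
  expect_equal(cg$t_stat, 0)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("group comparison has power at the study's effect sizes", {
  # GC3-like contrast: N(75.9, 1) vs N(70.1, 1), n = 15 per group
  set.seed(99)
  hits <- sum(vapply(1:100, function(i) {
    compare_groups(rnorm(15, 75.9, 1), rnorm(15, 70.1, 1))$p_value < 0.001
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("significance stars follow the report conventions", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
               c("", "*", "**", "***", ""))
})
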