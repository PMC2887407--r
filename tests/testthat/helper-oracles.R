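# Independent reference implementations used as oracles. These deliberately
# take the dumbest correct route (explicit enumeration, nested loops) and
# share no code with the package internals they check.

oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  codons <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases)
    codons <- c(codons, paste0(b1, b2, b3))
  aa <- Biostrings::GENETIC_CODE[codons]
  list(codons = codons, aa = aa, sense = codons[aa != "*"])
})

# parsimony informativeness of one nucleotide column, straight from the
# definition
oracle_informative_column <- function(col) {
  col <- col[col %in% c("A", "C", "G", "T")]
  counts <- sapply(c("A", "C", "G", "T"), function(b) sum(col == b))
  sum(counts >= 2) >= 2
}

# NG86 site fractions of one codon by neighbour enumeration
oracle_ng86_sites <- function(codon) {
  aa0 <- oracle_code$aa[[codon]]
  syn <- 0
  for (pos in 1:3) {
    n_syn <- 0; n_cnt <- 0
    for (b in c("T", "C", "A", "G")) {
      if (substr(codon, pos, pos) == b) next
      nb <- codon
      substr(nb, pos, pos) <- b
      if (oracle_code$aa[[nb]] == "*") next
      n_cnt <- n_cnt + 1
      if (oracle_code$aa[[nb]] == aa0) n_syn <- n_syn + 1
    }
    if (n_cnt > 0) syn <- syn + n_syn / n_cnt
  }
  c(syn, 3 - syn)
}

# NG86 synonymous/nonsynonymous differences between two codons: recursive
# depth-first enumeration of substitution orders, skipping paths through
# stops
oracle_ng86_diffs <- function(a, b) {
  paths <- list()
  walk <- function(cur, sd, nd) {
    if (cur == b) {
      paths[[length(paths) + 1]] <<- c(sd, nd)
      return(invisible())
    }
    for (pos in 1:3) {
      if (substr(cur, pos, pos) == substr(b, pos, pos)) next
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (oracle_code$aa[[nxt]] == "*") next
      if (oracle_code$aa[[nxt]] == oracle_code$aa[[cur]])
        walk(nxt, sd + 1, nd)
      else walk(nxt, sd, nd + 1)
    }
  }
  walk(a, 0, 0)
  if (length(paths) == 0) return(c(NA_real_, NA_real_))
  colMeans(do.call(rbind, paths))
}

# full NG86 pair computation from the two oracles above
oracle_ng86_pair <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    d <- oracle_ng86_diffs(ca[i], cb[i])
    if (!is.finite(d[1])) next
    sa <- oracle_ng86_sites(ca[i]); sb <- oracle_ng86_sites(cb[i])
    S <- S + (sa[1] + sb[1]) / 2
    N <- N + (sa[2] + sb[2]) / 2
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       dS = jc(Sd / S), dN = jc(Nd / N))
}

# brute-force codon likelihood of a 3-taxon rooted tree
# ((A:t1,B:t2):t3,C:t4) by summing over both internal node states
oracle_loglik_3taxa <- function(aln, t1, t2, t3, t4, kappa, omega, pi) {
  m <- codon_model(kappa, pi)
  Q <- build_rate_matrix(m, omega)
  P1 <- transition_probabilities(Q, t1, m)
  P2 <- transition_probabilities(Q, t2, m)
  P3 <- transition_probabilities(Q, t3, m)
  P4 <- transition_probabilities(Q, t4, m)
  sense <- oracle_code$sense
  states <- sapply(aln$sequences, function(s) {
    match(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)), sense)
  })
  pi <- unname(pi)
  ll <- 0
  for (h in seq_len(nrow(states))) {
    L <- 0
    for (r in 1:61) for (n in 1:61)
      L <- L + pi[r] * P3[r, n] * P1[n, states[h, 1]] *
        P2[n, states[h, 2]] * P4[r, states[h, 3]]
    ll <- ll + log(L)
  }
  ll
}

# Wright's ENC directly from codon counts (single pass, no package helpers)
oracle_enc <- function(seq) {
  cods <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  cods <- cods[cods %in% oracle_code$sense]
  aa <- oracle_code$aa[cods]
  fam_size <- table(oracle_code$aa[oracle_code$sense])
  Fk <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (a in unique(aa)) {
    k <- fam_size[[a]]
    if (k == 1) next
    n <- sum(aa == a)
    if (n < 2) next
    p <- table(cods[aa == a]) / n
    Fk[[as.character(k)]] <- c(Fk[[as.character(k)]],
                               (n * sum(p^2) - 1) / (n - 1))
  }
  Fbar <- sapply(Fk, function(v) if (length(v)) max(mean(v), 1e-6) else NA)
  if (is.na(Fbar["3"])) Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  min(2 + 9 / Fbar["2"] + 1 / Fbar["3"] + 5 / Fbar["4"] + 3 / Fbar["6"], 61)
}

# small random codon alignment (valid, no stops)
random_codon_alignment <- function(n_seq, n_codons, seed = 1) {
  set.seed(seed)
  sense <- oracle_code$sense
  seqs <- replicate(n_seq, paste(sample(sense, n_codons, TRUE), collapse = ""))
  codon_alignment(paste0("s", seq_len(n_seq)), seqs)
}

# one draw from a flat Dirichlet (simplex point)
rdirichlet1 <- function(n) {
  x <- stats::rgamma(n, shape = 1)
  x / sum(x)
}

# split a nucleotide string into codons
split_codons_chr <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}
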