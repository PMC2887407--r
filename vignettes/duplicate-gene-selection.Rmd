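---
title: "Models and methods for selection analysis of gene duplicates"
author: "paralogsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for selection analysis of gene duplicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

After a gene duplication, the two copies may keep the ancestral function
under purifying selection, may diverge asymmetrically when constraint
relaxes on one copy, or one copy may decay into a pseudogene. The classical
way to distinguish these fates from sequence data is to estimate the
nonsynonymous/synonymous rate ratio omega = dN/dS on an alignment of the two
paralog clades plus outgroups: omega << 1 indicates purifying selection,
omega near 1 neutral evolution, omega > 1 positive selection. `paralogsel`
implements that analysis end to end for in-frame codon alignments of a
duplicate gene pair: maximum-likelihood codon models partitioned over the
duplication history, counting-based divergence and rate tests, codon-usage
and composition contrasts, and synonymous-clock dating of the duplication,
together with a simulator that generates data with known truth so every
stage can be validated.

# The codon substitution model

The likelihood engine uses the Goldman–Yang codon model: a continuous-time
reversible Markov chain on the 61 sense codons of the standard code.
Instantaneous rates are nonzero only between codons differing at a single
position,

$$ q_{ij} = \pi_j \cdot \kappa^{\mathrm{ts}} \cdot \omega^{\mathrm{nonsyn}}, $$

where $\pi$ are equilibrium codon frequencies, $\kappa$ the
transition/transversion rate ratio, and $\omega$ multiplies nonsynonymous
changes. The generator is scaled so branch lengths are expected codon
substitutions per codon. Transition matrices come from the spectral
decomposition of the symmetrised generator (the model is reversible), and
alignment likelihoods from Felsenstein pruning over compressed codon site
patterns with per-pattern rescaling; the inner loops are small C++ kernels.
A codon containing a gap or an N is treated as missing data (its conditional
likelihood is 1 in every state), so an all-gap column contributes nothing.

Assumptions worth keeping in mind: one shared $\kappa$ and one $\pi$ for the
whole tree, no rate variation at synonymous sites, independence across
codons (no recombination or gene conversion within the alignment), and a
fixed, known tree topology — topology search is out of scope; the tree is an
input.

## Model families

*Branch models* partition $\omega$ over pre-assigned branch classes. For a
duplication the conventional classes are `pre` (branches predating the
duplication), `stem_g1`/`stem_g5` (the two branches immediately postdating
it) and `g1`/`g5` (the two crown clades). The ladder M0 (one ratio), M2r
(pre vs post), M3r (pre vs each paralog lineage), M4r (stems separated from
crowns), M5r (all five classes) and Mf (free ratios) is nested, so adjacent
models are compared by likelihood ratio tests with df equal to the
difference in the number of free omegas.

*Site models* let omega vary across codons via a mixture: M1 (nearly
neutral: $0<\omega_0<1$ plus $\omega_1=1$), M2 (adds $\omega_2 \ge 1$), M3
(K free discrete classes), M7 (beta-distributed omega on (0,1)) and M8 (beta
plus one class with $\omega \ge 1$). The beta models are discretised into 10
equal-probability categories at the quantile midpoints.

*Branch-site models* A and B combine both: background sites keep
$\omega_0$ (and $\omega_1$), while a fraction of sites switches to a
foreground ratio $\omega_2$ on designated branches. Model A constrains
$0<\omega_0<1$, $\omega_1=1$ and $\omega_2 \ge 1$; model B frees all three.
Model A is tested against M1 and model B against the two-class discrete
model.

Parameter counts reported as `n_params` count the model's free
omega/mixture parameters (1 for M0, 2 for M2r, ..., 2 for M1, 4 for M2, 5
for the 3-class discrete model, 4 for model A, 5 for model B); `n_free_total`
additionally counts kappa and branch lengths when they were estimated in
that fit. LRT degrees of freedom derive from the first convention, which is
how such model tables are conventionally printed; both counts are exposed
because free-ratio models are sometimes reported with branch lengths
included in "p".

## Fitting

`fit_codon_model()` maximises the likelihood with deterministic,
derivative-free-start multi-start optimisation:

- free omegas are optimised on a log scale in the box $[10^{-6}, 999]$;
  omegas constrained to (0,1) on a logit scale; omegas constrained $\ge 1$
  as $1+e^\theta$; class proportions through stick-breaking logits; beta
  shapes on a log scale in [0.005, 99]. An omega estimate at or above 990
  is reported in `unbounded_params` and rendered as infinite in tables.
- starts: each omega-type parameter is started at 0.05, 0.5 and 2. With
  fixed branch lengths all three starts are refined fully (mixture surfaces
  can be multimodal); when branch lengths are estimated, the starts are
  scanned and the best refined, since the expensive part is the
  branch-length optimisation that follows.
- branch lengths, when estimated, are initialised from the tree (or, if the
  tree carries none, from a least-squares fit to pairwise Jukes–Cantor
  distances), first rescaled by a single factor optimised jointly with the
  global parameters, then refined by cycles of per-branch Brent
  optimisation (each branch against cached partial likelihoods at its two
  ends) alternating with re-optimisation of the global parameters until the
  log-likelihood improves by less than `outer_tol` (default $10^{-5}$).
- the customary workflow — and the default of `run_full_analysis()` — is to
  estimate branch lengths and kappa once under M0 and hold them fixed for
  every other model. This deviates from tools that re-estimate branch
  lengths under every model; at the alignment sizes this package targets
  (hundreds of codons), re-estimation mostly adds variance to the very
  parameters the LRTs condition on. A fit with `branch_lengths =
  "estimate"` is available for every model when wanted.

Codon frequencies default to F3x4 (position-specific nucleotide frequencies
multiplied and renormalised over sense codons), with equal and
empirical-codon options. F3x4 frequencies are floored at $10^{-8}$ so short
alignments that happen to miss a base at one codon position cannot zero the
likelihood. The site-pattern engine, the per-branch caching and these
transforms are internal; only the natural-scale estimates surface.

Site identification under mixture models uses naive empirical Bayes (NEB):
the posterior probability of class $k$ at site $h$ is $p_k L_h(k) / \sum_j
p_j L_h(j)$ at the ML estimates, and sites whose summed posterior over
classes with foreground omega > 1 reaches 0.95 are flagged. NEB ignores the
sampling error of the estimated parameters (the Bayes empirical Bayes
refinement is deliberately out of scope), so flags on small alignments
should be read as hypotheses; output is labelled `method = "NEB"`.

# Counting-based statistics

`ng86_pair()` implements Nei–Gojobori (1986) counting: per-codon synonymous
site fractions by neighbour enumeration (changes to stop codons are excluded
from the per-position denominator, and synonymous plus nonsynonymous sites
sum to exactly 3), pairwise differences averaged over all minimal
substitution pathways with pathways through stops excluded (a codon pair
whose every pathway crosses a stop is dropped with a warning), pairwise
deletion of gapped/ambiguous codons, and the Jukes–Cantor correction
$d=-\tfrac34\log(1-\tfrac43 p)$. Proportions $\ge 3/4$ are reported as
saturated (`NA`), and dN/dS with $d_S=0$ is undefined rather than infinite
so window means never absorb non-finite values. `jc_distance()` applies the
same correction to raw nucleotide mismatch. `sliding_window()` profiles K,
dN and mean per-pair dN/dS in codon-aligned windows (default 30 bp at 9-bp
steps, the resolution customary for sub-gene selection profiles).

`tajima_rrt()` is Tajima's one-degree relative rate test on nucleotide
sites: m1 counts sites where only the first ingroup differs, m2 where only
the second does, and $(m_1-m_2)^2/(m_1+m_2)$ is referred to chi-square with
1 df. The reported lineage rate ratio is m1/m2, the quantity the test is
built on. Group contrasts of per-sequence statistics (GC3, ENC, dN, dS) use
Welch's unequal-variance t-test.

`enc()` is Wright's effective number of codons with the bias-corrected
homozygosity $F=(n\sum p_i^2-1)/(n-1)$ per amino acid (requiring $n \ge 2$),
class means over 2-, 3-, 4- and 6-fold families (isoleucine alone is
3-fold; leucine, serine and arginine stay intact as 6-fold), the
$(\bar F_2+\bar F_4)/2$ imputation for a missing 3-fold class, a reduced
formula borrowing the mean inverse homozygosity when another class is
entirely absent, and clamping at 61. Because $F$ carries an $O(1/n)$
correction, ENC is only asymptotically invariant to concatenating a
sequence with itself; the test suite checks the achievable bound.

`clock_date()` converts a calibrated ortholog synonymous distance into a
rate ($r = d_S/2T$) and a paralog distance into a duplication age
($t = d_S^{par}/2r$); values are reported unrounded plus rounded to the
nearest million years, the precision at which such estimates are usually
quoted.

# The simulator and what passing tests mean

`simulate_codon_alignment()` evolves codon states along a labelled tree by
drawing, per branch and site, from the transition matrix built with that
branch's class omega — one categorical draw per site from $P(t)$, which is
exact for the model (only endpoint states matter, so no event-by-event
simulation is needed). Site classes for mixture regimes are drawn once at
the root and inherited; branch-site regimes switch a per-site-flagged subset
to the foreground omega on foreground branches. Identical spec and seed give
byte-identical FASTA.

The default study-shaped preset (`duplication_m3r`) emulates the data
regime the package is aimed at: 14 taxa (two paralog clades of 7 and 6
species plus a pre-duplication outgroup), 87 codons (261 bp), kappa 2,
GC3-biased codon frequencies (target 0.759, matching strongly GC3-biased
grass coding sequence), and branch-partitioned purifying selection with
omega 0.044 before the duplication and 0.118 / 0.060 along the two
paralogs. Tree depths (crown 0.105, stem 0.18, outgroup 0.5 expected codon
substitutions per codon) were calibrated once so the counting-method dS
between the paralog clades is about 0.55 and within-clade dS about
0.13–0.17, the divergence levels typical of a grass whole-genome-duplication
pair dated near the origin of the family; they are fixed defaults, not
tuning knobs.

What the simulator does *not* emulate — and therefore what green tests do
not certify about real data: indels and alignment error (gaps only enter
via user input), intron evolution, gene conversion between paralogs,
recombination, codon-usage differences *between* the clades (one pi drives
the whole tree, so the ENC/GC3 group contrast on simulated data is null by
construction and only exercises the reporting path), selection on
synonymous sites, and lineage-specific kappa or frequency drift.

# Validation design

Every nontrivial computation is checked against an independent route on
small instances: pruning likelihoods against brute-force summation over all
internal-node states on 3-taxon, 5-codon alignments; NG86 counts against a
recursive pathway-enumeration oracle; ENC against a direct single-pass
formula; the parsimony-informativeness rule against a per-column
re-implementation. Property tests cover reversibility and scaling of the
generator, Chapman–Kolmogorov and stationarity of $P(t)$, the pulley
principle (rerooting invariance), order invariances, and the model-nesting
lattice (a larger model never fits worse than a model nested in it, to
optimizer tolerance).

Statistical behaviour is validated by simulation at the study's dimensions:
one-ratio fits on 14-taxon, 2000-codon data recover omega = 0.055 within
±0.01; three-ratio fits recover (0.044, 0.118, 0.060) within ±30% relative
error; the two-ratio-versus-one-ratio LRT holds its nominal 5% size on
null data (7 taxa × 200 codons, 100 replicates); the relative rate test
holds its size on equal-rate data; and the generator hits its GC3 and
paralog-dS targets at 5000 codons. The replicate counts (25 for the
recovery suites, 100 for the LRT calibration) and the reduced problem sizes
were chosen as the smallest designs whose binomial tolerance still
distinguishes the nominal behaviour; the corresponding thresholds
(≥24/25, ≥23/25, ≤9/100) are the 95% binomial bands at those counts. The
replicated fits cap the branch-length refinement at three outer rounds:
past that point only the final decimals of the log-likelihood move, and the
omega estimates the suites measure are unchanged to five significant
figures.

# Numerical choices and edge cases

- Optimizer stopping: L-BFGS-B with `factr = 1e5` (about $10^{-8}$ relative
  on the log-likelihood), finite-difference step $10^{-5}$ on transformed
  parameters; outer branch-length cycles stop at $10^{-5}$ absolute
  improvement, 8 rounds maximum (`converged = FALSE` is reported, never
  silent).
- Proportion logits are bounded at $10^{-9}$ so that a richer model can
  push a class weight close enough to zero to reproduce its null within the
  nesting tolerance of $10^{-6}$ log-units.
- Zero-length branches use $P(0)=I$ exactly; per-pattern scaling keeps
  partial likelihoods in range on long alignments; transition-matrix
  entries are clamped at 0 against roundoff.
- Degenerate inputs have defined behaviour rather than errors where a value
  is meaningful: single-taxon likelihood is the stationary log-probability;
  identical sequences give dN = dS = 0 with undefined omega; a relative
  rate test with no unique differences is flagged undefined; constant
  groups compare with p = 1; ENC on a sequence with no family observed
  twice is flagged undefined.
- NJ classification roots the query+reference tree at a reference of
  another label and asks which label's references plus the query are
  monophyletic; when the query attaches at the junction between reference
  clades (where two groupings are simultaneously clades), the tie is broken
  by mean patristic distance, and exact ties stay "ambiguous". Queries
  sharing under 50% resolved positions with the references are excluded.

# Known limitations

The engine targets desk-scale alignments (tens of taxa, up to a few
thousand codons); the per-branch optimisation recomputes partials per edge,
which is quadratic in tree size and would want the standard incremental
update for hundreds of taxa. Kappa and codon frequencies are global; there
is no among-site synonymous rate variation; BEB site identification, clade
models and topology search are out of scope. Dating assumes a strict
synonymous clock with a single calibration and reports no confidence
interval — at the divergences involved the dominant uncertainty is the
calibration itself, and the linearity of the estimate in each input (tested
exactly) makes sensitivity analysis straightforward for the user.
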