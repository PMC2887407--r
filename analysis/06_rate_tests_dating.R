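#!/usr/bin/env Rscript
# Lineage rate asymmetry and duplication dating. Tajima relative rate tests
# compare each matched paralog pair against the pre-duplication outgroup;
# the molecular clock converts synonymous distances into a duplication age,
# shown both with the published ortholog/paralog distances (0.388/0.592 and
# 0.457/0.497 with a 50-MYA calibration) and with distances measured from
# the simulated dataset.

suppressPackageStartupMessages(library(paralogsel))

if (!file.exists("results/data/dup_5000codons.fasta"))
  stop("run analysis/01_simulate_dataset.R first")
aln <- read_codon_fasta("results/data/dup_5000codons.fasta")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

g1 <- grep("^g1_", aln$names, value = TRUE)
g5 <- grep("^g5_", aln$names, value = TRUE)
outg <- "outgroup"
seq_of <- function(id) aln$sequences[match(id, aln$names)]

n <- min(length(g1), length(g5))
rrt <- do.call(rbind, lapply(seq_len(n), function(i) {
  r <- tajima_rrt(seq_of(g1[i]), seq_of(g5[i]), seq_of(outg))
  data.frame(seq_g1 = g1[i], seq_g5 = g5[i], m1 = r$m1, m2 = r$m2,
             ratio_g1_g5 = round(r$ratio, 2), chi2 = round(r$chi2, 2),
             p_value = round(r$p_value, 3),
             stars = significance_stars(r$p_value))
}))
write.table(rrt, "results/tables/rrt.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(rrt, row.names = FALSE)
message(sprintf(
  "paralog-1 evolved %.2fx faster than paralog-5 on average (truth: ",
  mean(rrt$ratio_g1_g5)), "omega 0.118 vs 0.060 on a shared tree)")

# dating with the published distances
hi <- clock_date(0.388, 0.592, 50)
lo <- clock_date(0.457, 0.497, 50)
message(sprintf(
  "published distances date the duplication at %d ~ %d MYA",
  lo$t_duplication_rounded, hi$t_duplication_rounded))

# dating with distances measured from the simulation: ortholog dS proxied
# by the deepest within-clade pair, paralog dS by a cross-clade pair
ds_or <- ng86_pair(seq_of(g1[1]), seq_of(g1[length(g1)]))$dS
ds_pa <- ng86_pair(seq_of(g1[1]), seq_of(g5[1]))$dS
sim_date <- clock_date(ds_or, ds_pa, 50)
message(sprintf(
  "simulated distances (dS ortholog %.3f, paralog %.3f) date it at %d MYA",
  ds_or, ds_pa, sim_date$t_duplication_rounded))
jsonlite::write_json(
  list(published_upper = unclass(hi), published_lower = unclass(lo),
       simulated = unclass(sim_date)),
  "results/tables/clock.json", auto_unbox = TRUE, digits = NA)
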