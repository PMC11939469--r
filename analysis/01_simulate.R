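#!/usr/bin/env Rscript
# Simulate the study flock: 81 ewes of two breeds enrolled, a 5,000-SNP
# panel on 26 autosomes, and two 42-day feeding periods (growth on an
# alfalfa pellet, maintenance on alfalfa hay) with 74 and 70 completers.
# Writes the raw-data analogues every later step consumes.

suppressPackageStartupMessages(library(rfiflock))

out_dir <- "results/simdata"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- default_config()
set.seed(cfg$seed)

G <- simulate_genotypes(n_animals = 81, n_snps = 5000,
                        n_chromosomes = 26, n_breeds = 2, fst = 0.05,
                        seed = cfg$seed)
sim <- simulate_flock(G, sim_config(), seed = cfg$seed + 1L)

for (p in c("p1", "p2")) {
  write_series(sim$weights[[p]], file.path(out_dir,
                                           paste0("weights_", p, ".csv")),
               "weight_kg")
  write_series(sim$intakes[[p]], file.path(out_dir,
                                           paste0("intakes_", p, ".csv")),
               "intake_kg")
}
utils::write.csv(sim$covariates, file.path(out_dir, "covariates.csv"),
                 row.names = FALSE, quote = FALSE)
write_plink_binary(G, file.path(out_dir, "genotypes"))
utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(
  data.frame(causal_snp = attr(sim$truth, "causal_snp"),
             effect_p1 = attr(sim$truth, "causal_effect")[1],
             effect_p2 = attr(sim$truth, "causal_effect")[2]),
  file.path(out_dir, "causal.tsv"), sep = "\t", row.names = FALSE,
  quote = FALSE)
write_config(cfg, file.path(out_dir, "config.yaml"))

tr <- sim$truth
cat("flock:", nrow(tr), "enrolled;", sum(tr$in_period1),
    "completed period 1;", sum(tr$in_period2), "period 2\n")
cat("panel:", length(G$snp_ids), "SNPs; causal SNP",
    attr(tr, "causal_snp"), "effect (kg DM/d per allele)",
    paste(signif(attr(tr, "causal_effect"), 3), collapse = " / "),
    "by period\n")
cat("true ADG p1:", round(mean(tr$adg_p1), 3), "+/-",
    round(sd(tr$adg_p1), 3), " p2:", round(mean(tr$adg_p2), 3), "+/-",
    round(sd(tr$adg_p2), 3), "kg/d\n")
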