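#!/usr/bin/env Rscript
# Descriptive statistics: within-period trait correlation matrices,
# between-period correlations, Welch period comparisons, and RFI
# repeatability (REML + parametric bootstrap).

suppressPackageStartupMessages(library(rfiflock))

cfg <- read_config("results/simdata/config.yaml")
ph <- lapply(1:2, function(p) {
  utils::read.table(sprintf("results/rfi_period%d.tsv", p), header = TRUE,
                    sep = "\t", colClasses = c(animal_id = "character"))
})
traits <- c("MTBW", "MBW", "ADG", "DMI", "RFI", "pwwt_ebv")

flat <- function(cm) {
  data.frame(trait1 = rep(rownames(cm$r), ncol(cm$r)),
             trait2 = rep(colnames(cm$r), each = nrow(cm$r)),
             r = as.vector(cm$r), p = as.vector(cm$p),
             significant = as.vector(cm$significant))
}
for (p in 1:2) {
  cm <- correlation_matrix(ph[[p]], traits, alpha = cfg$alpha)
  utils::write.table(flat(cm),
                     sprintf("results/correlations_period%d.tsv", p),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf(
    "period %d: corr(MTBW, MBW) = %.3f; corr(DMI, RFI) = %.3f; corr(MTBW, EBV) = %.3f\n",
    p, cm$r["MTBW", "MBW"], cm$r["DMI", "RFI"], cm$r["MTBW", "pwwt_ebv"]))
}

bt <- between_period_correlations(ph[[1]], ph[[2]],
                                  traits = c("MTBW", "MBW", "ADG", "DMI",
                                             "RFI"), alpha = cfg$alpha)
utils::write.table(bt, "results/correlations_between.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("between periods: RFI r =", round(bt$r[bt$trait == "RFI"], 3),
    "; MTBW r =", round(bt$r[bt$trait == "MTBW"], 3), "\n")

cmp <- do.call(rbind, lapply(c("MTBW", "MBW", "ADG", "DMI", "RFI"),
  function(tr) {
    cp <- compare_periods(ph[[1]][[tr]], ph[[2]][[tr]])
    data.frame(trait = tr, mean_p1 = cp$mean1, mean_p2 = cp$mean2,
               t = cp$t, df = cp$df, p = cp$p)
  }))
utils::write.table(cmp, "results/period_comparison.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("MTBW gap:", round(cmp$mean_p2[1] - cmp$mean_p1[1], 1),
    "kg (p =", signif(cmp$p[1], 2), ")\n")

long <- rbind(data.frame(animal_id = ph[[1]]$animal_id, period = 1,
                         value = ph[[1]]$RFI),
              data.frame(animal_id = ph[[2]]$animal_id, period = 2,
                         value = ph[[2]]$RFI))
rep_est <- repeatability(long, n_boot = 1000, seed = cfg$seed)
print(rep_est)
utils::write.table(
  data.frame(R = rep_est$R, SE = rep_est$SE, ci_lo = rep_est$CI[1],
             ci_hi = rep_est$CI[2], n_animals = rep_est$n_animals,
             n_boot = rep_est$n_boot),
  "results/repeatability.tsv", sep = "\t", row.names = FALSE,
  quote = FALSE)
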