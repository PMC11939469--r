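#!/usr/bin/env Rscript
# Collate the headline numbers from every stage into one summary table.

tsv <- function(f) utils::read.table(file.path("results", f),
                                     header = TRUE, sep = "\t")
cmp <- tsv("period_comparison.tsv")
rep_est <- tsv("repeatability.tsv")
bt <- tsv("correlations_between.tsv")
models <- tsv("intake_models.tsv")
qc <- tsv("qc_report.tsv")

lines <- c(
  sprintf("MTBW gap between periods: %.1f kg (Welch p = %.2g)",
          cmp$mean_p2[cmp$trait == "MTBW"] - cmp$mean_p1[cmp$trait == "MTBW"],
          cmp$p[cmp$trait == "MTBW"]),
  sprintf("RFI SD by period: %.3f / %.3f kg DM per day",
          models$resid_sd[1], models$resid_sd[2]),
  sprintf("Between-period RFI correlation: %.3f",
          bt$r[bt$trait == "RFI"]),
  sprintf("RFI repeatability: %.3f +/- %.3f (95%% CI %.3f-%.3f)",
          rep_est$R, rep_est$SE, rep_est$ci_lo, rep_est$ci_hi),
  sprintf("SNPs kept after QC: %s of %s; individuals kept: %s of %s",
          qc$value[qc$metric == "n_snps_kept"],
          qc$value[qc$metric == "n_snps_in"],
          qc$value[qc$metric == "n_individuals_kept"],
          qc$value[qc$metric == "n_individuals_in"]))
for (trait in c("RFI", "DMI")) {
  hits <- tsv(sprintf("hits_%s.tsv", trait))
  lines <- c(lines, sprintf(
    "%s period-2 scan: %d genome-wide hit(s)%s", trait, nrow(hits),
    if (nrow(hits) > 0) {
      paste0(" at ", paste(sprintf("%s (chr%s:%d, window %d-%d)",
                                   hits$snp_id, hits$chrom, hits$pos_bp,
                                   hits$window_start, hits$window_end),
                           collapse = "; "))
    } else ""))
}
writeLines(lines)
writeLines(lines, "results/summary.txt")
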