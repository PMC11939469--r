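#' Genotype quality control
#'
#' Applies the panel filters in a fixed, logged order: (1) SNPs flagged
#' multi-allelic at read time, (2) SNPs with call rate below
#' `snp_call_rate_min`, (3) individuals with call rate (over the SNPs
#' surviving 1-2) below `ind_call_rate_min`, (4) SNPs whose minor allele
#' frequency — recomputed on the retained individuals — falls below
#' `maf_min`. All removals are strict `<`: a SNP at exactly the call-rate
#' or MAF threshold is kept. The order matters because removing
#' individuals shifts borderline MAFs, so it is fixed rather than left to
#' chance.
#'
#' @param G A `genotype_matrix`.
#' @param snp_call_rate_min,ind_call_rate_min,maf_min Thresholds
#'   (defaults 0.90 / 0.90 / 0.05).
#' @return List with the filtered `genotype_matrix` (`G`) and a
#'   `qc_report` (class) itemizing counts removed by reason; reasons are
#'   disjoint under the precedence above.
#' @export
qc_filter <- function(G, snp_call_rate_min = 0.90,
                      ind_call_rate_min = 0.90, maf_min = 0.05) {
  n_in <- length(G$animal_ids)
  m_in <- length(G$snp_ids)

  rm_multi <- which(G$multiallelic)
  calls <- G$calls
  snp_cr <- colMeans(!is.na(calls))
  rm_callrate <- setdiff(which(snp_cr < snp_call_rate_min), rm_multi)
  snp_keep1 <- setdiff(seq_len(m_in), union(rm_multi, rm_callrate))

  ind_cr <- rowMeans(!is.na(calls[, snp_keep1, drop = FALSE]))
  rm_ind <- which(ind_cr < ind_call_rate_min)
  ind_keep <- setdiff(seq_len(n_in), rm_ind)
  if (length(ind_keep) == 0L) {
    stop("empty-panel error: all individuals removed by QC",
         call. = FALSE)
  }

  sub <- calls[ind_keep, snp_keep1, drop = FALSE]
  f1 <- colMeans(sub, na.rm = TRUE) / 2
  maf <- pmin(f1, 1 - f1)
  maf[is.nan(maf)] <- 0
  rm_maf <- snp_keep1[maf < maf_min]
  snp_keep <- setdiff(snp_keep1, rm_maf)
  if (length(snp_keep) == 0L) {
    stop("empty-panel error: all SNPs removed by QC", call. = FALSE)
  }

  Gout <- genotype_matrix(calls[ind_keep, snp_keep, drop = FALSE],
                          G$animal_ids[ind_keep], G$snp_ids[snp_keep],
                          G$chrom[snp_keep], G$pos_bp[snp_keep],
                          G$a1[snp_keep], G$a2[snp_keep],
                          G$multiallelic[snp_keep])
  report <- structure(list(
    n_snps_in = m_in,
    n_snps_removed_multiallelic = length(rm_multi),
    n_snps_removed_call_rate = length(rm_callrate),
    n_snps_removed_maf = length(rm_maf),
    n_snps_kept = length(snp_keep),
    n_individuals_in = n_in,
    n_individuals_removed = length(rm_ind),
    n_individuals_kept = length(ind_keep),
    removed_snps = G$snp_ids[sort(c(rm_multi, rm_callrate, rm_maf))],
    removed_individuals = G$animal_ids[rm_ind],
    thresholds = c(snp_call_rate_min = snp_call_rate_min,
                   ind_call_rate_min = ind_call_rate_min,
                   maf_min = maf_min)), class = "qc_report")
  list(G = Gout, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", x$n_snps_in, "SNPs in ->", x$n_snps_kept, "kept (",
      x$n_snps_removed_multiallelic, "multi-allelic,",
      x$n_snps_removed_call_rate, "call rate,",
      x$n_snps_removed_maf, "MAF );",
      x$n_individuals_in, "individuals ->", x$n_individuals_kept,
      "kept\n")
  invisible(x)
}

#' Additive allele dosages with mean imputation
#'
#' Converts calls to minor-allele counts (0/1/2) and imputes missing
#' calls with the SNP's mean observed dosage — the convention that keeps
#' one spectral transform valid for every SNP in the mixed-model scan.
#' Imputation preserves each SNP's observed allele frequency exactly.
#'
#' @param G A post-QC `genotype_matrix` (A1 = minor allele).
#' @return Numeric matrix, animals x SNPs, values in [0, 2], with
#'   dimnames.
#' @export
allele_dosage <- function(G) {
  D <- G$calls * 1.0
  mu <- colMeans(D, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na_idx <- which(is.na(D), arr.ind = TRUE)
  if (nrow(na_idx) > 0L) D[na_idx] <- mu[na_idx[, 2L]]
  D
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `K = Z Z' / (2 * sum_j p_j (1 - p_j))` where `Z` is the dosage matrix
#' column-centered by twice the observed allele frequency `p_j`.
#' Monomorphic SNPs contribute nothing and are skipped. The result is
#' symmetric and positive semi-definite with diagonal near 1 for
#' unrelated, unstructured panels.
#'
#' @param dosage Dosage matrix from [allele_dosage()]; at least 2 animals
#'   and one polymorphic SNP.
#' @return List of class `grm`: `matrix` (symmetric, dimnamed by animal)
#'   and `n_snps_used`.
#' @export
compute_grm <- function(dosage) {
  if (nrow(dosage) < 2L) {
    stop("insufficient-data error: GRM needs >= 2 animals", call. = FALSE)
  }
  p <- colMeans(dosage) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    stop("insufficient-data error: no polymorphic SNPs for GRM",
         call. = FALSE)
  }
  Z <- sweep(dosage[, poly, drop = FALSE], 2L, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(Z) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(dosage), rownames(dosage))
  structure(list(matrix = K, n_snps_used = sum(poly)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM:", nrow(x$matrix), "animals from", x$n_snps_used,
      "polymorphic SNPs; mean diagonal",
      sprintf("%.3f", mean(diag(x$matrix))), "\n")
  invisible(x)
}
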