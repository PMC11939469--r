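test_that("QC removals match exhaustive enumeration on the toy panel", {
  G <- qc_toy()
  res <- qc_filter(G)
  oracle <- qc_oracle(G)
  expect_equal(match(res$G$snp_ids, G$snp_ids), oracle$kept_snps)
  expect_equal(res$report$n_individuals_removed, length(oracle$removed_inds))
  expect_equal(res$report$n_snps_removed_multiallelic, length(oracle$multi))
  expect_equal(res$report$n_snps_removed_call_rate, length(oracle$low_cr))
  expect_equal(res$report$n_snps_removed_maf,
               length(oracle$low_maf))
  # bookkeeping identities: in = removed + kept on both axes
  r <- res$report
  expect_equal(r$n_snps_in,
               r$n_snps_removed_multiallelic + r$n_snps_removed_call_rate +
                 r$n_snps_removed_maf + r$n_snps_kept)
  expect_equal(r$n_individuals_in,
               r$n_individuals_removed + r$n_individuals_kept)
})

test_that("QC thresholds are strict: exact boundary values are kept", {
  # MAF exactly 0.05: 1 minor allele in 10 animals
  calls <- cbind(c(1L, rep(0L, 9)), rep(1L, 10))
  G <- genotype_matrix(calls, sprintf("a%d", 1:10), c("s1", "s2"),
                       c("1", "1"), c(1L, 2L), c("A", "A"), c("G", "G"))
  res <- qc_filter(G)
  expect_true("s1" %in% res$G$snp_ids)
  # SNP call rate exactly 0.90: 9/10 observed
  calls2 <- cbind(c(NA, rep(1L, 9)), rep(1L, 10))
  G2 <- genotype_matrix(calls2, sprintf("a%d", 1:10), c("s1", "s2"),
                        c("1", "1"), c(1L, 2L), c("A", "A"), c("G", "G"))
  res2 <- qc_filter(G2, maf_min = 0.01)
  expect_true("s1" %in% res2$G$snp_ids)
})

test_that("clean panels pass QC untouched", {
  G <- simulate_genotypes(30, 50, n_chromosomes = 2,
                          maf_range = c(0.3, 0.5), seed = 3)
  res <- qc_filter(G)
  expect_equal(res$report$n_snps_kept, 50)
  expect_equal(res$report$n_individuals_removed, 0L)
})

test_that("dosages code minor-allele counts and impute the SNP mean", {
  G <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L, 2L, NA), 3, 2),
                       sprintf("a%d", 1:3), c("s1", "s2"), c("1", "1"),
                       c(1L, 2L), c("A", "A"), c("G", "G"))
  D <- allele_dosage(G)
  expect_equal(unname(D[, 1]), c(0, 1, 2))
  expect_equal(unname(D[3, 2]), 1.0)        # mean of (0, 2)
  # imputation preserves the observed allele frequency exactly
  expect_equal(mean(D[, 2]) / 2, mean(c(0, 2)) / 2)
})

test_that("GRM has Gram structure: duplicates, PSD, diagonal near 1", {
  G <- simulate_genotypes(40, 400, n_chromosomes = 2, fst = 0, seed = 17)
  D <- allele_dosage(G)
  D2 <- rbind(D, D[1, ])                    # duplicate animal
  rownames(D2) <- c(rownames(D), "dup")
  K <- compute_grm(D2)$matrix
  expect_equal(K[1, nrow(K)], K[1, 1], tolerance = 1e-12)
  expect_equal(K[nrow(K), nrow(K)], K[1, 1], tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  expect_equal(K, t(K))
})

test_that("mean GRM diagonal is near 1 for a large unstructured panel", {
  G <- simulate_genotypes(200, 5000, n_chromosomes = 5, fst = 0,
                          seed = 19)
  K <- compute_grm(allele_dosage(G))$matrix
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
})

test_that("identity kinship collapses the mixed model to OLS", {
  set.seed(23)
  n <- 50
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + rnorm(n)
  K <- diag(n)
  vc <- fit_null(y, X, K)
  # sigma2_g and sigma2_e are not separately identifiable; the total
  # must match the OLS residual variance
  ols <- lm.fit(X, y)
  s2_ols <- sum(ols$residuals^2) / (n - 2)
  expect_equal(vc$sigma2_g * (1 + vc$delta), s2_ols, tolerance = 1e-6)
  # and per-SNP tests equal plain OLS exactly
  g <- matrix(rbinom(n, 2, 0.3), n, 1)
  res <- snp_scan(y, X, g, vc)
  fit <- lm(y ~ X[, 2] + g)
  sm <- summary(fit)$coefficients
  expect_equal(res$effect, sm["g", 1], tolerance = 1e-8)
  expect_equal(res$p, sm["g", 4], tolerance = 1e-8)
})

test_that("spectral REML log-likelihood matches the dense-matrix evaluation", {
  set.seed(29)
  n <- 40
  G <- simulate_genotypes(n, 300, n_chromosomes = 2, seed = 29)
  K <- compute_grm(allele_dosage(G))$matrix
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  vc <- fit_null(y, X, K)
  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  Ut <- t(eig$vectors)
  ys <- drop(Ut %*% y); Xs <- Ut %*% X
  spectral_ll <- function(delta) {
    d <- lambda + delta; w <- 1 / d
    XtHX <- crossprod(Xs, Xs * w)
    beta <- solve(XtHX, crossprod(Xs, ys * w))
    r <- ys - drop(Xs %*% beta)
    s2 <- sum(r^2 * w) / (n - 2)
    -0.5 * ((n - 2) * (log(2 * pi * s2) + 1) + sum(log(d)) +
              determinant(XtHX, TRUE)$modulus -
              determinant(crossprod(X), TRUE)$modulus)
  }
  for (delta in exp(runif(10, -3, 3))) {
    expect_equal(as.numeric(spectral_ll(delta)),
                 as.numeric(dense_reml_loglik(y, X, K, delta)),
                 tolerance = 1e-8)
  }
})

test_that("REML recovers variance components on a structured kinship", {
  set.seed(31)
  n <- 300
  G <- simulate_genotypes(n, 800, n_chromosomes = 4, fst = 0.15,
                          seed = 31)
  K <- compute_grm(allele_dosage(G))$matrix
  Ks <- t(chol(K + 1e-8 * diag(n)))
  ests <- sapply(1:20, function(rep) {
    u <- drop(Ks %*% rnorm(n))
    y <- 2 + u + rnorm(n)                  # sigma2_g = sigma2_e = 1
    vc <- fit_null(y, matrix(1, n, 1), K)
    c(vc$sigma2_g, vc$sigma2_e)
  })
  for (k in 1:2) {
    mc_se <- sd(ests[k, ]) / sqrt(ncol(ests))
    expect_lt(abs(mean(ests[k, ]) - 1), 3 * mc_se + 0.05)
  }
})

test_that("EMMAX scan matches the dense GLS oracle on small instances", {
  set.seed(37)
  n <- 60; m <- 100
  G <- simulate_genotypes(n, m, n_chromosomes = 2, fst = 0.1, seed = 37)
  D <- allele_dosage(G)
  K <- compute_grm(D)$matrix
  Ks <- t(chol(K + 1e-8 * diag(n)))
  y <- 1 + drop(Ks %*% rnorm(n)) + rnorm(n) + 0.8 * D[, 5]
  X <- cbind(1, rnorm(n))
  vc <- fit_null(y, X, K)
  res <- snp_scan(y, X, D, vc, G = G)
  for (j in c(1, 5, 23, 57, 100)) {
    oracle <- dense_gls_snp(y, X, D[, j], K, vc$sigma2_g, vc$sigma2_e)
    expect_equal(res$effect[j], oracle$effect, tolerance = 1e-6)
    expect_equal(res$se[j], oracle$se, tolerance = 1e-6)
    expect_equal(-log10(res$p[j]), -log10(oracle$p), tolerance = 1e-6)
  }
})

test_that("scan results are invariant to SNP and animal permutations", {
  set.seed(41)
  n <- 40; m <- 60
  G <- simulate_genotypes(n, m, n_chromosomes = 2, seed = 41)
  D <- allele_dosage(G)
  K <- compute_grm(D)$matrix
  y <- rnorm(n) + D[, 3]
  X <- matrix(1, n, 1)
  vc <- fit_null(y, X, K)
  res <- snp_scan(y, X, D, vc)
  # SNP column order
  perm <- sample(m)
  res_p <- snp_scan(y, X, D[, perm], vc)
  expect_equal(res_p$p, res$p[perm], tolerance = 1e-10)
  # animal row order, applied consistently to y, X, K (refit null)
  rp <- sample(n)
  vc2 <- fit_null(y[rp], X[rp, , drop = FALSE], K[rp, rp])
  res_r <- snp_scan(y[rp], X[rp, , drop = FALSE], D[rp, ], vc2)
  expect_equal(res_r$p, res$p, tolerance = 1e-6)
})

test_that("a SNP collinear with covariates degrades gracefully", {
  set.seed(43)
  n <- 30
  x <- rnorm(n)
  X <- cbind(1, x)
  D <- cbind(snpA = 2 * x + 3, snpB = rbinom(n, 2, 0.4))
  y <- rnorm(n)
  vc <- fit_null(y, X, diag(n))
  res <- snp_scan(y, X, D, vc)
  expect_true(res$degenerate[1])
  expect_equal(res$effect[1], 0)
  expect_equal(res$p[1], 1)
  expect_false(res$degenerate[2])
})

test_that("Bonferroni threshold is alpha over the retained SNP count", {
  expect_equal(bonferroni_threshold(44855), 0.05 / 44855)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20), 2.5e-3)
  expect_error(bonferroni_threshold(0), "m >= 1")
})

test_that("Manhattan table orders chromosomes and reports 1 Mb hit windows", {
  res <- data.frame(
    snp_id = c("sX", "s2", "s1", "s10"),
    chrom = c("X", "2", "1", "10"),
    pos_bp = c(500L, 68812505L, 1000L, 200L),
    effect = 1, se = 1, t = 1,
    p = c(0.5, 1e-8, 0.2, 0.9),
    neg_log10_p = -log10(c(0.5, 1e-8, 0.2, 0.9)),
    significant = FALSE, degenerate = FALSE)
  attr(res, "bonferroni") <- 1e-6
  mt <- manhattan_table(res)
  expect_equal(mt$table$chrom, c("1", "2", "10", "X"))
  expect_true(all(diff(mt$table$cum_pos) > 0))
  expect_equal(nrow(mt$hits), 1)
  expect_equal(mt$hits$window_start, 67812505L)
  expect_equal(mt$hits$window_end, 69812505L)
  expect_equal(mt$threshold_line, 6)
  # no hit below threshold -> empty list, full table retained
  res2 <- res; res2$p[2] <- 0.5
  res2$neg_log10_p <- -log10(res2$p)
  mt2 <- manhattan_table(res2, threshold = 1e-6)
  expect_equal(nrow(mt2$hits), 0)
  expect_equal(nrow(mt2$table), 4)
})

test_that("the full scan wrapper finds a strong simulated causal SNP", {
  set.seed(47)
  n <- 67; m <- 600
  G <- simulate_genotypes(n, m, n_chromosomes = 5, seed = 47)
  D <- allele_dosage(G)
  K <- compute_grm(D)$matrix
  Ks <- t(chol(K + 1e-8 * diag(n)))
  causal <- 250
  g <- D[, causal]
  beta <- sqrt(0.25 * 1 / var(g) / 0.75)   # ~25% of phenotypic variance
  mtbw <- rnorm(n, 27.8, 4.4)
  pheno <- data.frame(animal_id = G$animal_ids,
                      RFI = beta * g + 0.5 * drop(Ks %*% rnorm(n)) +
                        rnorm(n, 0, sqrt(0.75)),
                      MTBW = mtbw)
  res <- gwas_scan(G, pheno, "RFI", covariates = "MTBW")
  expect_lte(rank(res$p)[causal], 10)      # causal SNP in the top 10
  expect_s3_class(attr(res, "vc"), "variance_components")
})
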