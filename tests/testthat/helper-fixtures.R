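# Shared fixtures, built in code at test time.

# A small simulated flock reused across test files (deterministic).
small_flock <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      G <- simulate_genotypes(60, 300, n_chromosomes = 5, seed = 11)
      cache <<- list(G = G,
                     sim = simulate_flock(
                       G, sim_config(n_complete = c(55L, 50L)), seed = 12))
    }
    cache
  }
})

# Noise-free simulation config: weighing and intake noise off, RFI off.
noiseless_config <- function(n_complete = c(28L, 25L)) {
  sim_config(n_complete = n_complete, weigh_noise_sd = 0,
             intake_noise_sd = 0, rfi_sd = c(0, 0), repeatability = 0)
}

p1_window <- list(start_day = 0, end_day = 42, dm_fraction = 0.906)
p2_window <- list(start_day = 0, end_day = 42, dm_fraction = 0.897)

# Balanced one-way ANOVA intraclass correlation, computed from mean
# squares by hand -- independent oracle for the REML repeatability.
anova_icc <- function(long) {
  groups <- split(long$value, long$animal_id)
  k <- unique(lengths(groups))
  stopifnot(length(k) == 1L)
  a <- length(groups)
  gm <- mean(long$value)
  means <- vapply(groups, mean, 0)
  msb <- k * sum((means - gm)^2) / (a - 1)
  msw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2))) /
    (a * (k - 1))
  s2a <- max((msb - msw) / k, 0)
  s2a / (s2a + msw)
}

# Dense-matrix REML log-likelihood (explicit solves), the independent
# oracle for the spectral shortcut in fit_null().
dense_reml_loglik <- function(y, X, K, delta) {
  n <- length(y)
  p <- ncol(X)
  H <- K + delta * diag(n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  beta <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% beta
  R <- drop(t(r) %*% Hi %*% r)
  s2 <- R / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
            determinant(H, logarithm = TRUE)$modulus +
            determinant(XtHiX, logarithm = TRUE)$modulus -
            determinant(crossprod(X), logarithm = TRUE)$modulus)
}

# Dense GLS single-SNP test with an explicit covariance inverse -- the
# brute-force oracle for snp_scan().
dense_gls_snp <- function(y, X, g, K, sigma2_g, sigma2_e) {
  n <- length(y)
  V <- sigma2_g * K + sigma2_e * diag(n)
  L <- chol(V)
  W <- cbind(X, g)
  yt <- backsolve(L, y, transpose = TRUE)
  Wt <- backsolve(L, W, transpose = TRUE)
  fit <- lm.fit(Wt, yt)
  j <- ncol(W)
  df <- n - fit$rank
  s2 <- sum(fit$residuals^2) / df
  XtXi <- chol2inv(qr.R(fit$qr))
  se <- sqrt(s2 * XtXi[j, j])
  tstat <- unname(fit$coefficients[j]) / se
  list(effect = unname(fit$coefficients[j]), se = se, t = tstat,
       p = 2 * pt(-abs(tstat), df))
}

# 10-SNP x 6-animal toy panel exercising every QC rule at once.
qc_toy <- function() {
  calls <- matrix(1L, 6, 10)
  calls[, 1] <- c(0L, 1L, 2L, 0L, 1L, 2L)   # clean
  calls[, 2] <- c(0L, 0L, 1L, 1L, 2L, 2L)   # flagged multi-allelic below
  calls[1:2, 3] <- NA                        # call rate 4/6 < 0.9
  calls[, 4] <- c(0L, 0L, 0L, 0L, 0L, 1L)   # MAF 1/12 = 0.083 kept
  calls[, 5] <- c(0L, 0L, 0L, 0L, 0L, 0L)   # MAF 0 -> removed
  calls[, 6] <- c(1L, 0L, 2L, 1L, 0L, 2L)   # clean
  calls[, 7] <- c(0L, 1L, 0L, 0L, 0L, 0L)   # MAF depends on kept animals
  calls[, 8] <- c(2L, 1L, 0L, 2L, 1L, 0L)   # flagged multi-allelic below
  calls[6, 9] <- NA                          # call rate 5/6 = 0.833 < 0.9
  calls[, 10] <- c(0L, 1L, 1L, 0L, 0L, 1L)  # clean
  # animal 1 additionally missing 3 of 10 SNPs -> low individual call rate
  calls[1, c(1, 2, 6)] <- NA
  multi <- rep(FALSE, 10)
  multi[c(2, 8)] <- TRUE
  genotype_matrix(calls, sprintf("an%d", 1:6), sprintf("s%02d", 1:10),
                  rep("1", 10), seq(100L, 1000L, by = 100L),
                  rep("A", 10), rep("G", 10), multi)
}

# brute-force re-derivation of the QC outcome, straight from the rules
qc_oracle <- function(G, snp_cr = 0.9, ind_cr = 0.9, maf = 0.05) {
  m <- ncol(G$calls); n <- nrow(G$calls)
  multi <- which(G$multiallelic)
  cr <- sapply(seq_len(m), function(j) mean(!is.na(G$calls[, j])))
  low_cr <- setdiff(which(cr < snp_cr), multi)
  snps1 <- setdiff(seq_len(m), c(multi, low_cr))
  icr <- sapply(seq_len(n), function(i) {
    mean(!is.na(G$calls[i, snps1]))
  })
  bad_ind <- which(icr < ind_cr)
  inds <- setdiff(seq_len(n), bad_ind)
  low_maf <- Filter(function(j) {
    f <- mean(G$calls[inds, j], na.rm = TRUE) / 2
    min(f, 1 - f) < maf
  }, snps1)
  list(kept_snps = setdiff(snps1, low_maf), removed_inds = bad_ind,
       multi = multi, low_cr = low_cr, low_maf = unlist(low_maf))
}
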