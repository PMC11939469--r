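#' Within-period trait correlation matrix
#'
#' Pearson correlations between all trait pairs on pairwise-complete
#' observations, with two-sided t-based p-values and a significance flag
#' at the chosen level.
#'
#' @param pheno Phenotype table (one row per animal).
#' @param traits Character vector of numeric columns to correlate.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A list with matrices `r`, `p`, `n` (complete pairs) and
#'   logical `significant`; `r` has unit diagonal.
#' @export
correlation_matrix <- function(pheno,
                               traits = c("MTBW", "MBW", "ADG", "DMI",
                                          "RFI", "pwwt_ebv"),
                               alpha = 0.05) {
  traits <- intersect(traits, names(pheno))
  k <- length(traits)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- pheno[[traits[i]]]
      y <- pheno[[traits[j]]]
      ok <- is.finite(x) & is.finite(y)
      nmat[i, j] <- sum(ok)
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      if (sum(ok) < 3L) next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, n = nmat, significant = p < alpha)
}

#' Between-period trait correlations
#'
#' Correlates each trait's period-1 value with its period-2 value across
#' the animals present in both tables; per trait, animals missing either
#' value are excluded.
#'
#' @param pheno1,pheno2 Phenotype tables for the two periods.
#' @param traits Traits to correlate.
#' @param alpha Significance level for the flag.
#' @return Data.frame with `trait`, `r`, `p`, `n`, `significant`.
#' @export
between_period_correlations <- function(pheno1, pheno2,
                                        traits = c("MTBW", "MBW", "ADG",
                                                   "DMI", "RFI"),
                                        alpha = 0.05) {
  both <- merge(pheno1, pheno2, by = "animal_id",
                suffixes = c(".p1", ".p2"))
  out <- lapply(traits, function(tr) {
    x <- both[[paste0(tr, ".p1")]]
    y <- both[[paste0(tr, ".p2")]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      return(data.frame(trait = tr, r = NA_real_, p = NA_real_,
                        n = sum(ok), significant = NA))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(trait = tr, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), significant = ct$p.value < alpha)
  })
  do.call(rbind, out)
}

#' Compare a trait between periods
#'
#' Welch (unequal-variance) two-sample two-tailed t-test; the trait SDs
#' in this design differ up to four-fold between physiological periods,
#' so the pooled-variance test would be miscalibrated.
#'
#' @param x1,x2 Trait values in period 1 and period 2.
#' @return List with `t`, `df`, `p`, `mean1`, `mean2`.
#' @export
compare_periods <- function(x1, x2) {
  x1 <- x1[is.finite(x1)]
  x2 <- x2[is.finite(x2)]
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("insufficient-data error: >= 2 values per period required",
         call. = FALSE)
  }
  tt <- stats::t.test(x1, x2, var.equal = FALSE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean1 = mean(x1), mean2 = mean(x2))
}

#' Repeatability (intraclass correlation) with parametric bootstrap
#'
#' Fits the one-way random-intercept model `value ~ 1 + (1 | animal)` by
#' REML and reports `R = var_animal / (var_animal + var_residual)` — the
#' proportion of variance attributable to permanent between-animal
#' differences. Uncertainty comes from a parametric bootstrap:
#' `n_boot` datasets are resimulated from the fitted variances on the
#' observed design, refitted, and the SE and percentile 95% CI taken
#' from the bootstrap distribution. A boundary fit (no between-animal
#' variance) returns `R = 0` rather than failing.
#'
#' By default raw trait values enter the model even when the two periods
#' have unequal variances, matching common practice; `standardize = TRUE`
#' z-scores values within period first (the imbalance shrinks R, so the
#' two options answer different questions).
#'
#' @param long Data.frame with columns `animal_id`, `period`, `value`;
#'   at least 3 animals with 2 or more periods each.
#' @param n_boot Parametric bootstrap replicates (default 1000).
#' @param seed Optional integer seed; a fixed seed makes the bootstrap
#'   bit-reproducible. `NULL` (default) leaves the RNG stream untouched.
#' @param standardize Z-score values within period before fitting.
#' @return A list of class `repeatability`: `R`, `SE`, `CI` (percentile
#'   95%), `var_animal`, `var_residual`, `n_animals`, `n_boot`.
#' @export
repeatability <- function(long, n_boot = 1000L, seed = NULL,
                          standardize = FALSE) {
  long <- long[is.finite(long$value), , drop = FALSE]
  reps <- table(long$animal_id)
  if (sum(reps >= 2L) < 3L) {
    stop("insufficient-data error: repeatability needs >= 3 animals ",
         "with repeated measures", call. = FALSE)
  }
  if (standardize) {
    long$value <- stats::ave(long$value, long$period,
                             FUN = function(v) (v - mean(v)) / stats::sd(v))
  }
  fit <- fit_icc(long)
  if (!is.null(seed)) set.seed(seed)
  boot_R <- rep(NA_real_, n_boot)
  if (n_boot > 0L) {
    animals <- unique(long$animal_id)
    idx <- match(long$animal_id, animals)
    for (b in seq_len(n_boot)) {
      u <- stats::rnorm(length(animals), 0, sqrt(fit$var_animal))
      ysim <- fit$mu + u[idx] +
        stats::rnorm(nrow(long), 0, sqrt(fit$var_residual))
      sim <- long
      sim$value <- ysim
      boot_R[b] <- fit_icc(sim)$R
    }
  }
  structure(list(R = fit$R, SE = stats::sd(boot_R),
                 CI = if (n_boot > 0L) {
                   stats::quantile(boot_R, c(0.025, 0.975), names = FALSE)
                 } else c(NA_real_, NA_real_),
                 var_animal = fit$var_animal,
                 var_residual = fit$var_residual,
                 n_animals = length(unique(long$animal_id)),
                 n_boot = n_boot),
            class = "repeatability")
}

# One-way random-intercept REML fit; boundary (singular) fits give R = 0.
fit_icc <- function(long) {
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ 1 + (1 | animal_id), data = long, REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  va <- vc$vcov[vc$grp == "animal_id"]
  ve <- vc$vcov[vc$grp == "Residual"]
  va <- max(va, 0)
  list(R = if (va + ve > 0) va / (va + ve) else 0,
       var_animal = va, var_residual = ve,
       mu = unname(lme4::fixef(fit)[1L]))
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf(
    "repeatability R = %.3f (bootstrap SE %.3f, 95%% CI [%.3f, %.3f]), %d animals, %d bootstrap reps\n",
    x$R, x$SE, x$CI[1L], x$CI[2L], x$n_animals, x$n_boot))
  invisible(x)
}
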