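#' Fit the expected-intake model for one period
#'
#' A single multiple OLS regression, with intercept, of each animal's
#' daily dry-matter intake on its metabolic body weight and average daily
#' gain:
#'
#'   DMI = b0 + B1 * MBW + B2 * ADG + e
#'
#' The fitted value is the intake expected from body size and growth; the
#' residual is the animal's residual feed intake. Periods are fitted
#' entirely separately. Metabolic weight (MBW = MTBW^0.75) is the default
#' body-size regressor, the standard Koch-style choice; `size_regressor =
#' "MTBW"` substitutes raw mid-test weight for sensitivity analysis.
#'
#' @param pheno Phenotype table from [derive_phenotypes()]; at least 4
#'   animals with finite DMI, size regressor and ADG.
#' @param size_regressor `"MBW"` (default) or `"MTBW"`.
#' @return A list of class `intake_model`: `b0`, `B1` (kg DM/day per
#'   kg^0.75), `B2` (kg DM/day per kg/day), `resid_sd`, `r_squared`, `n`,
#'   `size_regressor`.
#' @export
fit_intake_model <- function(pheno, size_regressor = c("MBW", "MTBW")) {
  size_regressor <- match.arg(size_regressor)
  keep <- is.finite(pheno$DMI) & is.finite(pheno[[size_regressor]]) &
    is.finite(pheno$ADG)
  d <- pheno[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 4L) {
    stop("insufficient-data error: intake model needs >= 4 animals, got ",
         n, call. = FALSE)
  }
  X <- cbind(1, d[[size_regressor]], d$ADG)
  if (kappa(crossprod(X)) > 1e12) {
    stop("singular-fit error: size regressor and ADG are collinear",
         call. = FALSE)
  }
  fit <- stats::lm.fit(X, d$DMI)
  cf <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((d$DMI - mean(d$DMI))^2)
  structure(list(b0 = cf[1L], B1 = cf[2L], B2 = cf[3L],
                 resid_sd = sqrt(rss / (n - 3L)),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = n, size_regressor = size_regressor),
            class = "intake_model")
}

#' @export
print.intake_model <- function(x, ...) {
  cat(sprintf(
    "intake model (n = %d): DMI = %.4f + %.4f * %s + %.4f * ADG, resid SD %.4f, R^2 %.3f\n",
    x$n, x$b0, x$B1, x$size_regressor, x$B2, x$resid_sd, x$r_squared))
  invisible(x)
}

#' Compute residual feed intake
#'
#' RFI is each animal's observed DMI minus the intake expected from the
#' fitted model: `RFI_i = DMI_i - (b0 + B1 * size_i + B2 * ADG_i)`. By the
#' OLS residual identities the cohort mean RFI is 0 and RFI is
#' uncorrelated with both regressors; a lower (more negative) RFI means a
#' more efficient animal.
#'
#' @param pheno Phenotype table the model was fitted on.
#' @param model An `intake_model` from [fit_intake_model()].
#' @return `pheno` with the `RFI` column filled (kg DM/day); animals with
#'   non-finite inputs keep `NA`.
#' @export
compute_rfi <- function(pheno, model) {
  size <- pheno[[model$size_regressor]]
  expected <- model$b0 + model$B1 * size + model$B2 * pheno$ADG
  pheno$RFI <- pheno$DMI - expected
  pheno
}

#' Derive phenotypes and RFI for one period in one call
#'
#' Convenience wrapper: [derive_phenotypes()], [fit_intake_model()],
#' [compute_rfi()].
#'
#' @inheritParams derive_phenotypes
#' @inheritParams fit_intake_model
#' @return The completed phenotype table, with the fitted `intake_model`
#'   in attribute `intake_model`.
#' @export
period_phenotypes <- function(weights, intakes, period, covariates = NULL,
                              size_regressor = "MBW") {
  pheno <- derive_phenotypes(weights, intakes, period, covariates)
  model <- fit_intake_model(pheno, size_regressor)
  pheno <- compute_rfi(pheno, model)
  attr(pheno, "intake_model") <- model
  pheno
}
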