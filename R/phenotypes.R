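#' Fit the growth line for one animal
#'
#' Ordinary least squares of body weight on day within one experimental
#' period. The slope is the animal's average daily gain (ADG, kg/day); the
#' regression coefficients are reused downstream to predict mid-test body
#' weight.
#'
#' @param series Data.frame with columns `day` and `weight_kg` (one
#'   animal, one period); at least two distinct days required.
#' @return A list with `intercept` (kg at day 0), `slope` (ADG, kg/day),
#'   `resid_sd` (kg) and `n_obs`.
#' @export
fit_growth <- function(series) {
  if (nrow(series) < 2L || length(unique(series$day)) < 2L) {
    stop("insufficient-data error: >= 2 distinct weigh days required",
         call. = FALSE)
  }
  fit <- stats::lm(weight_kg ~ day, data = series)
  cf <- stats::coef(fit)
  n <- nrow(series)
  list(intercept = unname(cf[1L]), slope = unname(cf[2L]),
       resid_sd = if (n > 2L) sqrt(sum(fit$residuals^2) / (n - 2L)) else 0,
       n_obs = n)
}

#' Mid-test body weight from a growth fit
#'
#' Predicted weight at the temporal midpoint of the test window,
#' `intercept + slope * (start_day + end_day) / 2`.
#'
#' @param fit Output of [fit_growth()].
#' @param start_day,end_day Test window; `end_day > start_day`.
#' @return MTBW in kg.
#' @export
midtest_weight <- function(fit, start_day, end_day) {
  if (end_day <= start_day) {
    stop("configuration error: end_day must exceed start_day",
         call. = FALSE)
  }
  fit$intercept + fit$slope * (start_day + end_day) / 2
}

#' Metabolic body weight
#'
#' The allometric scaling of maintenance energy demand: MTBW raised to the
#' 0.75 power (kg^0.75).
#'
#' @param mtbw Mid-test body weight, kg, strictly positive.
#' @return MBW in kg^0.75.
#' @export
metabolic_weight <- function(mtbw) {
  if (any(!is.finite(mtbw)) || any(mtbw <= 0)) {
    stop("invalid MTBW: must be positive and finite", call. = FALSE)
  }
  mtbw^0.75
}

#' Convert an as-fed intake series to a dry-matter basis
#'
#' @param series Data.frame with columns `day` and `intake_kg` (as-fed).
#' @param dm_fraction Diet dry-matter fraction in (0, 1]; 0.906 for the
#'   growth-period pellet, 0.897 for the maintenance-period hay.
#' @return The series with `intake_kg` replaced by `dmi_kg` (kg DM).
#' @export
daily_dmi <- function(series, dm_fraction) {
  if (dm_fraction <= 0 || dm_fraction > 1) {
    stop("configuration error: dm_fraction must be in (0, 1]",
         call. = FALSE)
  }
  data.frame(day = series$day, dmi_kg = series$intake_kg * dm_fraction)
}

#' Scalar daily dry-matter intake for one animal
#'
#' Models daily DMI as a linear regression on day and reports the fitted
#' value at the midpoint of the test window — the intake analogue of
#' mid-test body weight. When the observed days are symmetric about the
#' midpoint this equals the plain arithmetic mean; `method = "mean"`
#' forces the plain mean instead.
#'
#' @param dmi Data.frame with columns `day` and `dmi_kg`.
#' @param start_day,end_day Test window.
#' @param method `"midpoint"` (default) or `"mean"`.
#' @return DMI in kg DM/day.
#' @export
mean_dmi <- function(dmi, start_day, end_day, method = c("midpoint", "mean")) {
  method <- match.arg(method)
  if (method == "mean") return(mean(dmi$dmi_kg))
  if (nrow(dmi) < 2L || length(unique(dmi$day)) < 2L) {
    stop("insufficient-data error: >= 2 observed intake days required",
         call. = FALSE)
  }
  fit <- stats::lm(dmi_kg ~ day, data = dmi)
  unname(stats::coef(fit)[1L] +
           stats::coef(fit)[2L] * (start_day + end_day) / 2)
}

#' Derive per-animal phenotypes for one experimental period
#'
#' Runs the full trait derivation for every animal with usable records:
#' ADG and MTBW from the weight-on-day regression, MBW = MTBW^0.75, and
#' the DMI scalar from the dry-matter intake regression. Animals with
#' fewer than two weight or intake observations are excluded from the
#' period and itemized in the `excluded` attribute with a reason, so no
#' record is ever dropped silently. RFI is left `NA` here and filled by
#' [compute_rfi()].
#'
#' @param weights,intakes Named lists of per-animal series, as returned by
#'   [read_weights()] / [read_intakes()] or [simulate_flock()].
#' @param period List with `start_day`, `end_day`, `dm_fraction`.
#' @param covariates Optional data.frame from [read_covariates()].
#' @param dmi_method Passed to [mean_dmi()].
#' @return A data.frame with one row per animal: `animal_id`, `ADG`,
#'   `MTBW`, `MBW`, `DMI`, `RFI` (NA), plus `breed` and `pwwt_ebv` when
#'   covariates are supplied. Attribute `excluded` lists removals.
#' @export
derive_phenotypes <- function(weights, intakes, period, covariates = NULL,
                              dmi_method = "midpoint") {
  ids <- intersect(names(weights), names(intakes))
  excluded <- data.frame(animal_id = character(), reason = character())
  rows <- list()
  for (id in ids) {
    w <- weights[[id]]
    f <- intakes[[id]]
    if (nrow(w) < 2L || length(unique(w$day)) < 2L) {
      excluded <- rbind(excluded, data.frame(
        animal_id = id, reason = "fewer than 2 weight observations"))
      next
    }
    if (nrow(f) < 2L) {
      excluded <- rbind(excluded, data.frame(
        animal_id = id, reason = "fewer than 2 intake observations"))
      next
    }
    gfit <- fit_growth(w)
    mtbw <- midtest_weight(gfit, period$start_day, period$end_day)
    dmi_series <- daily_dmi(f, period$dm_fraction)
    dmi <- mean_dmi(dmi_series, period$start_day, period$end_day,
                    method = dmi_method)
    rows[[id]] <- data.frame(animal_id = id, ADG = gfit$slope,
                             MTBW = mtbw, MBW = metabolic_weight(mtbw),
                             DMI = dmi, RFI = NA_real_,
                             stringsAsFactors = FALSE)
  }
  only_w <- setdiff(names(weights), names(intakes))
  if (length(only_w) > 0L) {
    excluded <- rbind(excluded, data.frame(
      animal_id = only_w, reason = "no intake records"))
  }
  pheno <- do.call(rbind, rows)
  rownames(pheno) <- NULL
  if (!is.null(covariates)) {
    pheno <- merge(pheno, covariates, by = "animal_id", all.x = TRUE,
                   sort = TRUE)
  }
  attr(pheno, "excluded") <- excluded
  pheno
}
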