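#' Read longitudinal weight records
#'
#' Reads a comma-separated table with header columns `animal_id`, `day`,
#' `weight_kg` and splits it into one weight series per animal. `day` is an
#' integer offset from the start of the experimental period (day 0), not a
#' calendar date. Rows with non-numeric, non-finite or non-positive weights
#' are rejected with an error naming the offending row, because a weight of
#' zero or below can only be a recording failure.
#'
#' @param path Path to a CSV file with columns `animal_id`, `day`,
#'   `weight_kg`.
#' @return A named list of weight series. Each element is a data.frame with
#'   columns `day` (integer, strictly increasing) and `weight_kg`
#'   (positive), named by `animal_id`.
#' @export
read_weights <- function(path) {
  df <- read_series_table(path, value_col = "weight_kg",
                          require_positive = TRUE)
  split_series(df, value_col = "weight_kg")
}

#' Read daily as-fed feed-intake records
#'
#' Reads a comma-separated table with columns `animal_id`, `day`,
#' `intake_kg` (as-fed kg, i.e. not yet corrected for moisture). Intakes
#' must be non-negative and finite; days must be unique per animal. Days an
#' animal recorded nothing are simply absent rows, never zeros: the feeder
#' records feed disappearance only when feeding occurs, so an imputed zero
#' would bias dry-matter intake downward.
#'
#' @param path Path to a CSV file with columns `animal_id`, `day`,
#'   `intake_kg`.
#' @return A named list of intake series (data.frames with `day`,
#'   `intake_kg`), named by animal id.
#' @export
read_intakes <- function(path) {
  df <- read_series_table(path, value_col = "intake_kg",
                          require_positive = FALSE)
  split_series(df, value_col = "intake_kg")
}

#' Read per-animal covariates
#'
#' @param path CSV with columns `animal_id`, `breed`, `pwwt_ebv`.
#' @return A data.frame with one row per animal.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal_id = "character"))
  need <- c("animal_id", "breed", "pwwt_ebv")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  if (anyDuplicated(df$animal_id)) {
    stop("duplicate-record error: repeated animal_id in ", path,
         call. = FALSE)
  }
  df[need]
}

#' Write a collection of series back to CSV
#'
#' Inverse of [read_weights()] / [read_intakes()]; a write-then-read round
#' trip reproduces the input exactly.
#'
#' @param series Named list of per-animal data.frames (`day` + value column).
#' @param path Output CSV path.
#' @param value_col Name of the value column (`"weight_kg"` or
#'   `"intake_kg"`).
#' @export
write_series <- function(series, path, value_col = "weight_kg") {
  rows <- lapply(names(series), function(id) {
    s <- series[[id]]
    # %.17g keeps enough digits that read-back reproduces every double
    data.frame(animal_id = id, day = s$day,
               v = sprintf("%.17g", s[[value_col]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[3L] <- value_col
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared reader: validates columns, numeric values, (animal, day) uniqueness.
read_series_table <- function(path, value_col, require_positive) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("animal_id", "day", value_col)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  day <- suppressWarnings(as.integer(df$day))
  val <- suppressWarnings(as.numeric(df[[value_col]]))
  bad_day <- which(is.na(day))
  if (length(bad_day) > 0L) {
    stop("format error: non-integer day at row ", bad_day[1L] + 1L,
         " of ", path, call. = FALSE)
  }
  bad <- which(is.na(val) | !is.finite(val) |
                 (if (require_positive) val <= 0 else val < 0))
  if (length(bad) > 0L) {
    stop("format error: invalid ", value_col, " value '",
         df[[value_col]][bad[1L]], "' at row ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  key <- paste(df$animal_id, day)
  if (anyDuplicated(key)) {
    dup <- key[which(duplicated(key))[1L]]
    stop("duplicate-record error: repeated (animal, day) pair [", dup,
         "] in ", path, call. = FALSE)
  }
  data.frame(animal_id = df$animal_id, day = day, value = val,
             stringsAsFactors = FALSE)
}

split_series <- function(df, value_col) {
  out <- lapply(split(df, df$animal_id), function(s) {
    s <- s[order(s$day), , drop = FALSE]
    res <- data.frame(day = s$day, v = s$value)
    names(res)[2L] <- value_col
    res
  })
  out[order(names(out))]
}

#' Default run configuration
#'
#' Bundles every tunable the pipeline uses: period windows and diet
#' dry-matter fractions, genotype QC thresholds, the significance level,
#' the GWAS covariate list, and the master random seed. All randomness in
#' the package flows from this one seed.
#'
#' The two diet dry-matter fractions default to the trial diets: 90.6%
#' for the alfalfa pellet fed in the growth period and 89.7% for the
#' alfalfa hay fed in the maintenance period.
#'
#' @param period1,period2 Lists with `start_day`, `end_day`,
#'   `dm_fraction` describing each 42-day collection window.
#' @param snp_call_rate_min,ind_call_rate_min,maf_min QC thresholds in
#'   (0, 1); removals are strict `<`, so a SNP exactly at a threshold is
#'   kept.
#' @param alpha Significance level for correlations and the Bonferroni
#'   family-wise level for the association scan.
#' @param covariates Character vector of fixed covariates for the scan
#'   (default `"MTBW"`, the headline model).
#' @param seed Master random seed (integer).
#' @return A list of class `rfi_config`.
#' @export
default_config <- function(period1 = list(start_day = 0L, end_day = 42L,
                                          dm_fraction = 0.906),
                           period2 = list(start_day = 0L, end_day = 42L,
                                          dm_fraction = 0.897),
                           snp_call_rate_min = 0.90,
                           ind_call_rate_min = 0.90,
                           maf_min = 0.05,
                           alpha = 0.05,
                           covariates = "MTBW",
                           seed = 20210830L) {
  for (p in list(period1, period2)) {
    if (p$end_day <= p$start_day) {
      stop("configuration error: period end_day must exceed start_day",
           call. = FALSE)
    }
    if (p$dm_fraction <= 0 || p$dm_fraction > 1) {
      stop("configuration error: dm_fraction must be in (0, 1]",
           call. = FALSE)
    }
  }
  for (thr in c(snp_call_rate_min, ind_call_rate_min, maf_min, alpha)) {
    if (thr <= 0 || thr >= 1) {
      stop("configuration error: thresholds must lie strictly in (0, 1)",
           call. = FALSE)
    }
  }
  structure(list(period1 = period1, period2 = period2,
                 snp_call_rate_min = snp_call_rate_min,
                 ind_call_rate_min = ind_call_rate_min,
                 maf_min = maf_min, alpha = alpha,
                 covariates = covariates, seed = as.integer(seed)),
            class = "rfi_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_config`, an `rfi_config` validated through
#'   [default_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param config An `rfi_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
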