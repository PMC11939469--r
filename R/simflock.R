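#' Simulate two-breed SNP genotypes
#'
#' Draws a biallelic SNP panel with Balding-Nichols breed structure:
#' ancestral minor-allele frequencies are uniform on `maf_range`, each
#' breed's frequency is a Beta draw around the ancestral value with
#' divergence `fst`, and genotypes are two independent allele draws from
#' the breed frequency. SNPs are assigned to chromosomes in equal blocks
#' with sorted positions. With `fst = 0` all breeds share the ancestral
#' frequencies exactly.
#'
#' @param n_animals,n_snps Panel dimensions.
#' @param n_chromosomes Number of autosomes to spread SNPs over (26, the
#'   ovine autosome count, by default).
#' @param maf_range Interval in (0, 0.5] for ancestral frequencies.
#' @param n_breeds Number of breeds; animals are split as evenly as
#'   possible (the trial's flock was two breeds of near-equal size).
#' @param fst Balding-Nichols divergence parameter in [0, 1).
#' @param seed Integer seed; the draw is bit-reproducible.
#' @return A `genotype_matrix` with a `breed` attribute (character vector
#'   per animal).
#' @export
simulate_genotypes <- function(n_animals, n_snps, n_chromosomes = 26L,
                               maf_range = c(0.05, 0.5), n_breeds = 2L,
                               fst = 0.05, seed = 1L) {
  if (n_snps < n_chromosomes) {
    stop("configuration error: need at least one SNP per chromosome",
         call. = FALSE)
  }
  stopifnot(maf_range[1L] > 0, maf_range[2L] <= 0.5, fst >= 0, fst < 1)
  set.seed(seed)
  p_anc <- stats::runif(n_snps, maf_range[1L], maf_range[2L])
  breed <- sort(rep(paste0("breed", seq_len(n_breeds)),
                    length.out = n_animals))
  calls <- matrix(NA_integer_, n_animals, n_snps)
  for (b in unique(breed)) {
    rows <- which(breed == b)
    if (fst > 0) {
      a <- (1 - fst) / fst
      p_b <- stats::rbeta(n_snps, p_anc * a, (1 - p_anc) * a)
    } else {
      p_b <- p_anc
    }
    calls[rows, ] <- matrix(
      stats::rbinom(length(rows) * n_snps, 2L,
                    rep(p_b, each = length(rows))),
      length(rows), n_snps)
  }
  per_chr <- rep(n_snps %/% n_chromosomes, n_chromosomes)
  extra <- n_snps %% n_chromosomes
  if (extra > 0L) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  chrom <- rep(as.character(seq_len(n_chromosomes)), times = per_chr)
  pos <- unlist(lapply(per_chr, function(k) {
    sort(sample.int(100000000L, k))
  }))
  ids <- sprintf("ewe%03d", seq_len(n_animals))
  snps <- sprintf("snp%05d", seq_len(n_snps))
  G <- genotype_matrix(calls, ids, snps, chrom, pos,
                       a1 = rep("A", n_snps), a2 = rep("G", n_snps))
  attr(G, "breed") <- stats::setNames(breed, ids)
  attr(G, "p_ancestral") <- p_anc
  G
}

#' Default simulation configuration for a two-period feeding trial
#'
#' The defaults emulate the trial the package models: 81 ewe lambs of two
#' breeds enrolled, 74 completing a 42-day growth period (weekly
#' weighings, alfalfa pellet at 90.6% dry matter, ADG 0.26 +/- 0.12
#' kg/day, mid-test weight 27.8 +/- 4.39 kg) and 70 returning for a
#' 42-day maintenance period roughly eight months later (alfalfa hay at
#' 89.7% DM, ADG -0.02 +/- 0.16 kg/day, mid-test weight 42.9 +/- 7.10
#' kg). True RFI has SD 0.24 kg DM/day in growth and 0.97 in maintenance,
#' with a between-period shared fraction (the target repeatability) of
#' 0.157 decomposed into polygenic, causal-SNP and permanent-environment
#' parts.
#'
#' @param n_complete Integer vector length 2: animals completing each
#'   period; attrition from the enrolled panel is uniform at random.
#' @param init_weight_mean,init_weight_sd,adg_mean,adg_sd Per-period
#'   moments (length-2 vectors, kg and kg/day).
#' @param weigh_days Weighing schedule (days within the period).
#' @param n_intake_days Length of the intake record (daily, from day 0).
#' @param weigh_noise_sd Scale-error SD on each weighing, kg.
#' @param intake_noise_sd Day-to-day intake noise SD, kg DM.
#' @param dm_fraction Per-period diet dry-matter fraction.
#' @param weight_cor Correlation of true initial body weight between the
#'   two periods (the same ewes return, heavier but still ranked much
#'   the same).
#' @param b0,B1,B2 Intake-model coefficients generating true expected
#'   intake (`b0` and `B1` per period — body size has more leverage on
#'   intake at maintenance than during growth; `B2` shared).
#' @param rfi_sd Per-period true RFI standard deviation, kg DM/day.
#' @param repeatability Shared fraction of RFI variance in each period;
#'   equals the between-period correlation of true RFI.
#' @param poly_frac,causal_frac,pe_frac Decomposition of the shared RFI
#'   component into polygenic (GRM-structured), causal-SNP and permanent
#'   environment variance fractions; must sum to 1.
#' @param ebv_noise_mult PWWT EBV = true initial weight + noise with SD
#'   `ebv_noise_mult` times the initial-weight SD; the default 2.05 gives
#'   corr(MTBW, EBV) near 0.44 while leaving corr(RFI, EBV) at 0.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_complete = c(74L, 70L),
                       init_weight_mean = c(22.34, 43.32),
                       init_weight_sd = c(4.3, 7.0),
                       adg_mean = c(0.26, -0.02),
                       adg_sd = c(0.12, 0.16),
                       weigh_days = seq(0L, 42L, by = 7L),
                       n_intake_days = 43L,
                       weigh_noise_sd = 0.5,
                       intake_noise_sd = 0.15,
                       dm_fraction = c(0.906, 0.897),
                       weight_cor = 0.7,
                       b0 = c(-0.42, -3.49), B1 = c(0.18, 0.33),
                       B2 = 1.0,
                       rfi_sd = c(0.24, 0.97),
                       repeatability = 0.157,
                       poly_frac = 0.5, causal_frac = 0.25,
                       pe_frac = 0.25,
                       ebv_noise_mult = 2.05) {
  if (abs(poly_frac + causal_frac + pe_frac - 1) > 1e-8 ||
      any(c(poly_frac, causal_frac, pe_frac) < 0)) {
    stop("configuration error: shared-variance fractions must be ",
         "non-negative and sum to 1", call. = FALSE)
  }
  if (repeatability < 0 || repeatability > 1) {
    stop("configuration error: repeatability must lie in [0, 1]",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

# symmetric PSD square root via eigendecomposition, negative eigenvalues
# clipped at zero
matrix_sqrt <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Simulate a complete two-period feeding trial
#'
#' Generates weight and intake time series, covariates and the underlying
#' truth for every animal in a genotype panel. Per animal and period,
#' weight follows `initial + ADG * day` plus weighing noise, and daily
#' dry-matter intake follows the expected-intake model `b0 + B1 * MBW +
#' B2 * ADG` plus the animal's true RFI and day-to-day noise, converted
#' to an as-fed basis by dividing by the diet dry-matter fraction.
#'
#' True RFI in period p is `sd_p * (sqrt(r) * u_i + sqrt(1 - r) * z_ip)`,
#' centered per period, where the unit-variance shared component `u`
#' combines a polygenic draw with covariance proportional to the panel's
#' genomic relationship matrix, a causal-SNP dosage effect, and a
#' permanent-environment draw. The construction ties the association
#' scan's null covariance to the phenotype, exactly what the mixed model
#' assumes, and makes `r` both the per-period shared variance fraction
#' and the between-period correlation of true RFI.
#'
#' Attrition to the per-period cohort sizes is uniform at random, never
#' preferential on genotype; period-2 animals are a subset of period-1
#' completers.
#'
#' @param G A `genotype_matrix` from [simulate_genotypes()] (its `breed`
#'   attribute, when present, feeds the covariates table).
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole simulation is bit-reproducible.
#' @return A list with `weights` and `intakes` (each a list `p1`/`p2` of
#'   named per-animal series), `covariates` (animal_id, breed, pwwt_ebv),
#'   and `truth` — a data.frame of per-animal true ADG, initial weight
#'   and RFI per period plus the shared component, with attributes
#'   `causal_index`, `causal_snp` and `causal_effect` (realized kg DM/day
#'   per minor allele, per period).
#' @export
simulate_flock <- function(G, config = sim_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  ids <- G$animal_ids
  n <- length(ids)
  if (any(cfg$n_complete > n)) {
    stop("configuration error: n_complete exceeds panel size",
         call. = FALSE)
  }

  # shared RFI component: polygenic + causal SNP + permanent environment
  dos <- allele_dosage(G)
  K <- compute_grm(dos)
  poly <- as.vector(matrix_sqrt(K$matrix) %*% stats::rnorm(n))
  maf <- colMeans(dos) / 2
  eligible <- which(maf >= 0.1 & maf <= 0.5 & !G$multiallelic)
  causal_idx <- if (length(eligible) > 0) sample(eligible, 1L)
                else which.max(maf)
  causal_dos <- dos[, causal_idx]
  pe <- stats::rnorm(n)
  u <- sqrt(cfg$poly_frac) * standardize(poly) +
    sqrt(cfg$causal_frac) * standardize(causal_dos) +
    sqrt(cfg$pe_frac) * standardize(pe)
  u <- standardize(u)

  r <- cfg$repeatability
  rfi <- sapply(1:2, function(p) {
    raw <- cfg$rfi_sd[p] * (sqrt(r) * u +
                              sqrt(1 - r) * stats::rnorm(n))
    raw - mean(raw)
  })
  # realized per-allele causal effect on the period scale
  sd_d <- stats::sd(causal_dos)
  causal_effect <- if (sd_d > 0) {
    cfg$rfi_sd * sqrt(r) * sqrt(cfg$causal_frac) / sd_d
  } else c(0, 0)

  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- cfg$weight_cor
  init_w <- cbind(
    cfg$init_weight_mean[1L] + cfg$init_weight_sd[1L] * z1,
    cfg$init_weight_mean[2L] + cfg$init_weight_sd[2L] *
      (rho * z1 + sqrt(1 - rho^2) * z2))
  adg <- sapply(1:2, function(p) {
    stats::rnorm(n, cfg$adg_mean[p], cfg$adg_sd[p])
  })

  # uniform attrition: enrolled -> period-1 completers -> period-2
  keep1 <- sort(sample(n, cfg$n_complete[1L]))
  keep2 <- sort(sample(keep1, cfg$n_complete[2L]))
  keep <- list(keep1, keep2)

  weights <- intakes <- list()
  days_int <- seq(0L, cfg$n_intake_days - 1L)
  for (p in 1:2) {
    wl <- il <- list()
    for (i in keep[[p]]) {
      id <- ids[i]
      w <- init_w[i, p] + adg[i, p] * cfg$weigh_days +
        stats::rnorm(length(cfg$weigh_days), 0, cfg$weigh_noise_sd)
      wl[[id]] <- data.frame(day = cfg$weigh_days, weight_kg = w)
      mbw_true <- (init_w[i, p] +
                     adg[i, p] * mean(range(cfg$weigh_days)))^0.75
      dmi <- cfg$b0[p] + cfg$B1[p] * mbw_true + cfg$B2 * adg[i, p] +
        rfi[i, p] + stats::rnorm(length(days_int), 0, cfg$intake_noise_sd)
      dmi <- pmax(dmi, 0)
      il[[id]] <- data.frame(day = days_int,
                             intake_kg = dmi / cfg$dm_fraction[p])
    }
    weights[[paste0("p", p)]] <- wl
    intakes[[paste0("p", p)]] <- il
  }

  breed <- attr(G, "breed")
  if (is.null(breed)) breed <- stats::setNames(rep("breed1", n), ids)
  ebv <- init_w[, 1L] - mean(init_w[, 1L]) +
    stats::rnorm(n, 0, cfg$ebv_noise_mult * cfg$init_weight_sd[1L])
  covariates <- data.frame(animal_id = ids, breed = unname(breed[ids]),
                           pwwt_ebv = round(ebv, 3),
                           stringsAsFactors = FALSE)

  truth <- data.frame(animal_id = ids, breed = unname(breed[ids]),
                      init_weight_p1 = init_w[, 1L],
                      init_weight_p2 = init_w[, 2L],
                      adg_p1 = adg[, 1L], adg_p2 = adg[, 2L],
                      rfi_p1 = rfi[, 1L], rfi_p2 = rfi[, 2L],
                      shared = u,
                      in_period1 = seq_len(n) %in% keep1,
                      in_period2 = seq_len(n) %in% keep2,
                      stringsAsFactors = FALSE)
  attr(truth, "causal_index") <- causal_idx
  attr(truth, "causal_snp") <- G$snp_ids[causal_idx]
  attr(truth, "causal_effect") <- causal_effect
  list(weights = weights, intakes = intakes, covariates = covariates,
       truth = truth)
}

#' Simulate a phenotype cohort directly from the expected-intake model
#'
#' Draws metabolic weight and gain at given moments and generates DMI
#' from `DMI = b0 + B1 * MBW + B2 * ADG + e` with a chosen residual SD,
#' where `B1` is solved (with `B2 = 1`) so that the total DMI standard
#' deviation hits a target. Used to study how the intake-model residual
#' structure propagates into RFI correlations when the size/gain/intake
#' moments are known but individual records are not.
#'
#' @param n Cohort size.
#' @param mbw_mean,mbw_sd,adg_mean,adg_sd Trait moments (kg^0.75, kg/day).
#' @param resid_sd Residual SD of the generating model, kg DM/day.
#' @param total_sd Target total SD of DMI; must satisfy
#'   `total_sd^2 > resid_sd^2 + adg_sd^2` so a real `B1` exists.
#' @param dmi_mean Target mean DMI, kg DM/day.
#' @param match `"population"` (default) treats `resid_sd`/`total_sd` as
#'   population parameters, so realized cohort SDs fluctuate around
#'   them. `"sample"` conditions on the targets instead: the drawn
#'   residual vector is orthogonalized against the design and rescaled
#'   so the cohort's sample residual and total SDs equal the targets
#'   exactly — the right mode when the targets are themselves sample
#'   SDs printed for one realized cohort.
#' @return A phenotype-style data.frame (`animal_id`, `ADG`, `MTBW`,
#'   `MBW`, `DMI`, `RFI = NA`) ready for [fit_intake_model()].
#' @export
simulate_intake_cohort <- function(n, mbw_mean, mbw_sd, adg_mean, adg_sd,
                                   resid_sd, total_sd, dmi_mean = 2.0,
                                   match = c("population", "sample")) {
  match <- match.arg(match)
  fitted_var <- total_sd^2 - resid_sd^2 - adg_sd^2
  if (fitted_var <= 0) {
    stop("configuration error: total_sd^2 must exceed resid_sd^2 + ",
         "adg_sd^2 (B2 = 1)", call. = FALSE)
  }
  B1 <- sqrt(fitted_var) / mbw_sd
  mbw <- stats::rnorm(n, mbw_mean, mbw_sd)
  adg <- stats::rnorm(n, adg_mean, adg_sd)
  if (match == "population") {
    b0 <- dmi_mean - B1 * mbw_mean - adg_mean
    dmi <- b0 + B1 * mbw + adg + stats::rnorm(n, 0, resid_sd)
  } else {
    e <- stats::rnorm(n)
    e <- qr.resid(qr(cbind(1, mbw, adg)), e)
    e <- e / stats::sd(e) * resid_sd
    f <- B1 * mbw + adg
    fd <- (f - mean(f)) / stats::sd(f) * sqrt(total_sd^2 - resid_sd^2)
    dmi <- dmi_mean + fd + e
  }
  data.frame(animal_id = sprintf("a%04d", seq_len(n)),
             ADG = adg, MTBW = mbw^(4 / 3), MBW = mbw, DMI = dmi,
             RFI = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate repeated measures at a known repeatability
#'
#' Long-format data `value_ip = sqrt(R) * u_i + sqrt(1 - R) * e_ip`
#' (times `sqrt(total_var)`), so the intraclass correlation is exactly
#' `R` by construction.
#'
#' @param n_animals,n_periods Design size.
#' @param R True repeatability in [0, 1].
#' @param total_var Total variance of the measure.
#' @return Data.frame with `animal_id`, `period`, `value`.
#' @export
simulate_repeated <- function(n_animals, n_periods = 2L, R = 0.157,
                              total_var = 1) {
  u <- stats::rnorm(n_animals)
  value <- sqrt(total_var) *
    (sqrt(R) * rep(u, each = n_periods) +
       sqrt(1 - R) * stats::rnorm(n_animals * n_periods))
  data.frame(animal_id = rep(sprintf("a%04d", seq_len(n_animals)),
                             each = n_periods),
             period = rep(seq_len(n_periods), n_animals),
             value = value)
}
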