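#' REML variance components under the null polygenic model
#'
#' Fits `y = X b + u + e` with `u ~ (0, sigma2_g K)` and
#' `e ~ (0, sigma2_e I)` by restricted maximum likelihood. Writing
#' `delta = sigma2_e / sigma2_g`, the covariance is
#' `sigma2_g (K + delta I)`; the kinship eigendecomposition is computed
#' once and the REML log-likelihood, profiled over `sigma2_g` and the
#' fixed effects, is maximized in one dimension over `log(delta)` by a
#' grid search refined with Brent's method. A boundary solution
#' (`delta -> Inf`, i.e. no genetic variance) is returned, not errored:
#' downstream tests then reduce to ordinary least squares.
#'
#' @param y Phenotype vector (finite).
#' @param X Fixed-effect design matrix including the intercept column;
#'   full column rank.
#' @param K Symmetric kinship/GRM matrix (a `grm` or plain matrix)
#'   conformable with `y`.
#' @param log_delta_range Search interval for `log(delta)`.
#' @param n_grid Coarse grid size before Brent refinement.
#' @return A list of class `variance_components`: `sigma2_g`, `sigma2_e`,
#'   `delta`, `loglik` (REML, at the optimum), `h2` (= sigma2_g / total),
#'   plus the spectral decomposition reused by [snp_scan()].
#' @export
fit_null <- function(y, X, K, log_delta_range = c(-10, 10),
                     n_grid = 100L) {
  if (inherits(K, "grm")) K <- K$matrix
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (any(!is.finite(y))) {
    stop("invalid phenotype: non-finite values", call. = FALSE)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop("rank-deficient covariate design", call. = FALSE)
  }
  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  Ut <- t(eig$vectors)
  ys <- drop(Ut %*% y)
  Xs <- Ut %*% X
  ldet_XtX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  # profiled REML log-likelihood at a given log(delta)
  prof <- function(ld) {
    d <- lambda + exp(ld)
    w <- 1 / d
    XtHX <- crossprod(Xs, Xs * w)
    beta <- solve(XtHX, crossprod(Xs, ys * w))
    r <- ys - drop(Xs %*% beta)
    R <- sum(r^2 * w)
    s2 <- R / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(d)) +
              determinant(XtHX, logarithm = TRUE)$modulus - ldet_XtX)
  }
  grid <- seq(log_delta_range[1L], log_delta_range[2L],
              length.out = n_grid)
  ll <- vapply(grid, prof, 0)
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, n_grid)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  ld_hat <- opt$maximum
  # a true boundary optimum keeps the grid edge
  if (ll[i] > opt$objective) ld_hat <- grid[i]
  delta <- exp(ld_hat)
  d <- lambda + delta
  w <- 1 / d
  XtHX <- crossprod(Xs, Xs * w)
  beta <- solve(XtHX, crossprod(Xs, ys * w))
  r <- ys - drop(Xs %*% beta)
  s2g <- sum(r^2 * w) / (n - p)
  structure(list(sigma2_g = s2g, sigma2_e = s2g * delta, delta = delta,
                 loglik = prof(ld_hat),
                 h2 = 1 / (1 + delta),
                 beta_null = drop(beta),
                 eigen_values = lambda, eigen_Ut = Ut),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "REML variance components: sigma2_g = %.4g, sigma2_e = %.4g (delta = %.4g, h2 = %.3f), logLik %.3f\n",
    x$sigma2_g, x$sigma2_e, x$delta, x$h2, x$loglik))
  invisible(x)
}

#' Mixed-model association scan (EMMAX approximation)
#'
#' Tests each SNP by generalized least squares of the phenotype on
#' `[X | dosage_j]` under `V = sigma2_g K + sigma2_e I`, with the
#' variance components held fixed at the null fit — the EMMAX shortcut
#' that replaces per-SNP REML with a single spectral rotation. Inference
#' uses the exact small-sample Wald t with `n - rank([X | g])` degrees
#' of freedom rather than a normal approximation, appropriate for
#' panels of tens of animals. A SNP collinear with the covariates gets
#' effect 0, p = 1 and a degenerate flag.
#'
#' @param y Phenotype vector.
#' @param X Covariate design incl. intercept (same rows as `y`).
#' @param dosage Dosage matrix from [allele_dosage()] (animals x SNPs).
#' @param vc `variance_components` from [fit_null()] on the same `y`,
#'   `X`, kinship.
#' @param G Optional `genotype_matrix` supplying SNP map columns for the
#'   result table.
#' @param alpha Family-wise level for the Bonferroni flag.
#' @return Data.frame of class `gwas_result`: `snp_id`, `chrom`,
#'   `pos_bp`, `effect` (phenotype units per minor allele), `se`, `t`,
#'   `p`, `neg_log10_p`, `significant`, `degenerate`; attribute
#'   `bonferroni` holds the per-test threshold.
#' @export
snp_scan <- function(y, X, dosage, vc, G = NULL, alpha = 0.05) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  m <- ncol(dosage)
  stopifnot(nrow(dosage) == n, nrow(X) == n)
  w <- 1 / sqrt(vc$eigen_values + vc$delta)
  Tt <- vc$eigen_Ut * w            # rows scaled: T = diag(w) U'
  yt <- drop(Tt %*% y)
  Xt <- Tt %*% X
  Gt <- Tt %*% dosage
  qrX <- qr(Xt)
  p <- qrX$rank
  My <- qr.resid(qrX, yt)
  MG <- qr.resid(qrX, Gt)
  gss <- colSums(MG^2)
  gy <- colSums(MG * My)
  yss <- sum(My^2)
  df <- n - p - 1L
  tol <- max(gss, 1) * 1e-10
  ok <- gss > tol
  beta <- ifelse(ok, gy / gss, 0)
  rss <- pmax(yss - beta * gy, 0)
  se <- ifelse(ok, sqrt(rss / df / gss), NA_real_)
  tstat <- ifelse(ok, beta / se, 0)
  pval <- ifelse(ok, 2 * stats::pt(-abs(tstat), df), 1)
  thr <- bonferroni_threshold(m, alpha)
  snp_ids <- if (!is.null(G)) G$snp_ids else colnames(dosage)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%05d", seq_len(m))
  res <- data.frame(
    snp_id = snp_ids,
    chrom = if (!is.null(G)) G$chrom else NA_character_,
    pos_bp = if (!is.null(G)) G$pos_bp else NA_integer_,
    effect = beta, se = se, t = tstat, p = pval,
    neg_log10_p = -log10(pval),
    significant = pval < thr,
    degenerate = !ok,
    stringsAsFactors = FALSE)
  attr(res, "bonferroni") <- thr
  attr(res, "df") <- df
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Bonferroni per-test threshold
#'
#' @param m Number of tests (retained SNPs).
#' @param alpha Family-wise error level.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

#' Manhattan-plot table and significant-hit windows
#'
#' Lays chromosomes end to end (numeric labels ascending, non-numeric
#' labels last alphabetically) to give each SNP a cumulative genome
#' coordinate, carries -log10 p and the Bonferroni threshold line, and
#' reports each SNP below threshold with its candidate-gene window of
#' +/- `window_bp` around the position.
#'
#' @param results A `gwas_result` from [snp_scan()].
#' @param threshold Per-test p threshold (defaults to the scan's
#'   Bonferroni attribute).
#' @param window_bp Half-width of the candidate window (default 1 Mb).
#' @return List with `table` (snp_id, chrom, pos_bp, cum_pos,
#'   neg_log10_p, significant), `threshold_line` (-log10 threshold) and
#'   `hits` (flagged SNPs with `window_start`/`window_end`, floored at
#'   1).
#' @export
manhattan_table <- function(results, threshold = attr(results, "bonferroni"),
                            window_bp = 1000000L) {
  chr <- unique(results$chrom)
  num <- suppressWarnings(as.numeric(chr))
  ord <- order(is.na(num), num, chr)
  chr_levels <- chr[ord]
  res <- results[order(match(results$chrom, chr_levels), results$pos_bp), ]
  offsets <- c(0, cumsum(vapply(chr_levels, function(cc) {
    max(res$pos_bp[res$chrom == cc])
  }, 0)))
  names(offsets) <- c(chr_levels, "end")
  cum_pos <- res$pos_bp + offsets[match(res$chrom, chr_levels)]
  tab <- data.frame(snp_id = res$snp_id, chrom = res$chrom,
                    pos_bp = res$pos_bp, cum_pos = unname(cum_pos),
                    neg_log10_p = res$neg_log10_p,
                    significant = res$p < threshold,
                    stringsAsFactors = FALSE)
  hits <- res[res$p < threshold, , drop = FALSE]
  hits <- data.frame(hits[c("snp_id", "chrom", "pos_bp", "effect", "se",
                            "p")],
                     window_start = pmax(hits$pos_bp - window_bp, 1L),
                     window_end = hits$pos_bp + window_bp,
                     stringsAsFactors = FALSE)
  rownames(tab) <- rownames(hits) <- NULL
  list(table = tab, threshold_line = -log10(threshold), hits = hits)
}

#' Full mixed-model GWAS for one trait
#'
#' Convenience wrapper chaining [allele_dosage()], [compute_grm()],
#' [fit_null()] and [snp_scan()] for a phenotype table and trait name.
#' The headline model regresses the trait on an intercept plus the
#' requested covariate columns with the GRM as random effect.
#'
#' @param G Post-QC `genotype_matrix`.
#' @param pheno Phenotype table containing `animal_id`, the trait and
#'   covariates; only animals present in both the table and the panel
#'   are analyzed.
#' @param trait Column to scan (e.g. `"RFI"`, `"DMI"`).
#' @param covariates Covariate column names (default `"MTBW"`).
#' @param alpha Family-wise Bonferroni level.
#' @return A `gwas_result` (see [snp_scan()]) with the fitted
#'   `variance_components` in attribute `vc`.
#' @export
gwas_scan <- function(G, pheno, trait, covariates = "MTBW",
                      alpha = 0.05) {
  ids <- intersect(G$animal_ids, pheno$animal_id)
  pheno <- pheno[match(ids, pheno$animal_id), , drop = FALSE]
  ok <- is.finite(pheno[[trait]])
  for (cv in covariates) ok <- ok & is.finite(pheno[[cv]])
  ids <- ids[ok]
  pheno <- pheno[ok, , drop = FALSE]
  sel <- match(ids, G$animal_ids)
  Gs <- genotype_matrix(G$calls[sel, , drop = FALSE], ids, G$snp_ids,
                        G$chrom, G$pos_bp, G$a1, G$a2, G$multiallelic)
  dosage <- allele_dosage(Gs)
  K <- compute_grm(dosage)
  y <- pheno[[trait]]
  X <- cbind(intercept = 1,
             as.matrix(pheno[, covariates, drop = FALSE]))
  vc <- fit_null(y, X, K)
  res <- snp_scan(y, X, dosage, vc, G = Gs, alpha = alpha)
  attr(res, "vc") <- vc
  res
}
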