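test_that("correlation matrix is symmetric, unit-diagonal, with valid p", {
  sim <- small_flock()$sim
  ph <- period_phenotypes(sim$weights$p1, sim$intakes$p1, p1_window,
                          sim$covariates)
  cm <- correlation_matrix(ph)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, ncol(cm$r)))
  off <- cm$p[upper.tri(cm$p)]
  expect_true(all(off >= 0 & off <= 1))
  # MTBW and MBW are a monotone transform apart on a tight weight range
  expect_gt(cm$r["MTBW", "MBW"], 0.999)
})

test_that("small-table correlations match the textbook formula by brute force", {
  ph <- data.frame(animal_id = letters[1:5],
                   MTBW = c(25.1, 27.9, 30.2, 24.4, 28.8),
                   DMI = c(1.8, 2.1, 2.4, 1.7, 2.0))
  cm <- correlation_matrix(ph, traits = c("MTBW", "DMI"))
  x <- ph$MTBW; y <- ph$DMI; n <- 5
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), n - 2)
  expect_equal(cm$r["MTBW", "DMI"], r_hand, tolerance = 1e-12)
  expect_equal(cm$p["MTBW", "DMI"], p_hand, tolerance = 1e-12)
})

test_that("between-period correlations use shared animals and hit exact cases", {
  ph1 <- data.frame(animal_id = sprintf("a%02d", 1:20),
                    MTBW = rnorm(20, 27.8, 4.4))
  ph1$DMI <- 0.07 * ph1$MTBW + rnorm(20, 0, 0.1)
  ph2 <- ph1[1:15, ]                       # attrition
  bt <- between_period_correlations(ph1, ph2, traits = c("MTBW", "DMI"))
  expect_equal(bt$r, c(1, 1), tolerance = 1e-12)
  expect_equal(bt$n, c(15L, 15L))
  # independent periods: r centered near zero across replicates
  set.seed(33)
  rs <- replicate(200, {
    p1 <- data.frame(animal_id = 1:40, RFI = rnorm(40))
    p2 <- data.frame(animal_id = 1:40, RFI = rnorm(40))
    between_period_correlations(p1, p2, traits = "RFI")$r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(200))
})

test_that("between-period RFI correlation tracks the configured variance split", {
  set.seed(44)
  G <- simulate_genotypes(120, 80, n_chromosomes = 2, seed = 44)
  cfg <- sim_config(n_complete = c(120L, 120L))
  rs <- sapply(1:30, function(s) {
    sim <- simulate_flock(G, cfg, seed = 400 + s)
    ph1 <- period_phenotypes(sim$weights$p1, sim$intakes$p1, p1_window)
    ph2 <- period_phenotypes(sim$weights$p2, sim$intakes$p2, p2_window)
    between_period_correlations(ph1, ph2, traits = "RFI")$r
  })
  # estimation noise in derived RFI attenuates the correlation slightly;
  # the Monte-Carlo mean must sit near the configured 0.157
  expect_lt(abs(mean(rs) - cfg$repeatability),
            3 * sd(rs) / sqrt(length(rs)) + 0.02)
})

test_that("Welch comparison returns exact degenerate and separated cases", {
  x <- c(27.1, 28.3, 26.5, 29.0)
  cp <- compare_periods(x, x)
  expect_equal(cp$t, 0)
  expect_equal(cp$p, 1)
  set.seed(55)
  sig <- replicate(50, {
    compare_periods(rnorm(74, 27.8, 4.39), rnorm(70, 42.9, 7.10))$p
  })
  expect_true(all(sig < 0.05))             # 15 kg apart: always detected
  ns <- replicate(50, {
    compare_periods(rnorm(74, 2.01, 0.38), rnorm(70, 2.02, 1.19))$p
  })
  expect_gt(mean(ns > 0.05), 0.8)          # near-equal means: rarely flagged
  expect_error(compare_periods(1, c(1, 2)), "insufficient-data")
})

test_that("repeatability hits the exact boundary cases", {
  # identical within animal, different between -> R = 1
  long <- data.frame(animal_id = rep(letters[1:6], each = 2),
                     period = rep(1:2, 6),
                     value = rep(c(1, 3, 5, 7, 9, 11), each = 2))
  est <- repeatability(long, n_boot = 0)
  expect_equal(est$R, 1, tolerance = 1e-6)
  # i.i.d. values -> R near 0 (boundary handled, not errored)
  set.seed(66)
  long2 <- data.frame(animal_id = rep(sprintf("a%02d", 1:40), each = 2),
                      period = rep(1:2, 40), value = rnorm(80))
  est2 <- repeatability(long2, n_boot = 0)
  expect_lt(est2$R, 0.15)
})

test_that("REML repeatability equals the balanced one-way ANOVA ICC oracle", {
  set.seed(77)
  for (rep in 1:8) {
    long <- simulate_repeated(40, 2, R = runif(1, 0, 0.6))
    est <- repeatability(long, n_boot = 0)
    expect_lt(abs(est$R - anova_icc(long)), 1e-6)
  }
})

test_that("parametric bootstrap is reproducible and bounded", {
  set.seed(88)
  long <- simulate_repeated(30, 2, R = 0.3)
  e1 <- repeatability(long, n_boot = 100, seed = 5)
  e2 <- repeatability(long, n_boot = 100, seed = 5)
  expect_identical(e1$SE, e2$SE)
  expect_identical(e1$CI, e2$CI)
  expect_true(all(e1$CI >= 0 & e1$CI <= 1))
  expect_gt(e1$SE, 0)
})

test_that("within-period standardization changes R when period variances differ", {
  set.seed(99)
  long <- simulate_repeated(60, 2, R = 0.4)
  long$value[long$period == 2] <- long$value[long$period == 2] * 4
  raw <- repeatability(long, n_boot = 0)$R
  std <- repeatability(long, n_boot = 0, standardize = TRUE)$R
  expect_gt(std, raw)                      # imbalance shrinks raw R
})
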