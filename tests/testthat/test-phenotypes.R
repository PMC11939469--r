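test_that("growth fit recovers exact and two-point lines", {
  days <- seq(0, 42, by = 7)
  s <- data.frame(day = days, weight_kg = 30 + 0.2 * days)
  fit <- fit_growth(s)
  expect_equal(fit$intercept, 30)
  expect_equal(fit$slope, 0.2)

  s2 <- data.frame(day = c(0, 42), weight_kg = c(30, 38.4))
  expect_equal(fit_growth(s2)$slope, 0.2)

  expect_error(fit_growth(data.frame(day = 0, weight_kg = 30)),
               "insufficient-data")
})

test_that("growth slope matches a brute-force normal-equations solve", {
  set.seed(101)
  for (rep in 1:10) {
    days <- seq(0, 42, by = 7)
    w <- 28 + 0.26 * days + rnorm(length(days), 0, 0.5)
    fit <- fit_growth(data.frame(day = days, weight_kg = w))
    X <- cbind(1, days)
    beta <- solve(t(X) %*% X, t(X) %*% w)   # normal equations by hand
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  }
})

test_that("mid-test weight is the fitted value at the window midpoint", {
  fit <- list(intercept = 30, slope = 0.2)
  expect_equal(midtest_weight(fit, 0, 42), 34.2)
  expect_equal(midtest_weight(list(intercept = 25, slope = 0), 0, 42), 25)
  # exact-line series: MTBW equals the observed weight at day 21
  days <- seq(0, 42, by = 7)
  s <- data.frame(day = days, weight_kg = 30 + 0.2 * days)
  expect_equal(midtest_weight(fit_growth(s), 0, 42), 30 + 0.2 * 21)
  expect_error(midtest_weight(fit, 42, 0), "configuration error")
})

test_that("metabolic weight is MTBW^0.75 and strictly increasing", {
  expect_equal(metabolic_weight(16), 8)
  expect_equal(metabolic_weight(1), 1)
  # high-precision oracle via exp/log
  expect_equal(metabolic_weight(42.9), exp(0.75 * log(42.9)),
               tolerance = 1e-12)
  expect_equal(round(metabolic_weight(42.9), 1), 16.8)
  w <- sort(runif(50, 10, 60))
  expect_true(all(diff(metabolic_weight(w)) > 0))
  expect_error(metabolic_weight(-1), "positive")
})

test_that("dry-matter conversion multiplies by the diet DM fraction", {
  s <- data.frame(day = 0:1, intake_kg = c(2.0, 2.0))
  expect_equal(daily_dmi(s, 0.906)$dmi_kg, c(1.812, 1.812))
  expect_equal(daily_dmi(s, 0.897)$dmi_kg, c(1.794, 1.794))
  expect_equal(daily_dmi(s, 1.0)$dmi_kg, s$intake_kg)
  expect_error(daily_dmi(s, 1.2), "configuration error")
})

test_that("DMI scalar is the fitted midpoint and equals the mean under symmetry", {
  d <- data.frame(day = 0:42, dmi_kg = rep(2, 43))
  expect_equal(mean_dmi(d, 0, 42), 2)
  d2 <- data.frame(day = 0:42, dmi_kg = 1.8 + 0.01 * (0:42))
  expect_equal(mean_dmi(d2, 0, 42), 1.8 + 0.01 * 21)
  set.seed(5)
  d3 <- data.frame(day = 0:42, dmi_kg = 2 + rnorm(43, 0, 0.2))
  expect_equal(mean_dmi(d3, 0, 42), mean(d3$dmi_kg), tolerance = 1e-10)
  expect_equal(mean_dmi(d3, 0, 42, method = "mean"), mean(d3$dmi_kg))
})

test_that("growth and intake fits are day-shift equivariant", {
  set.seed(6)
  days <- seq(0, 42, by = 7)
  w <- 30 + 0.2 * days + rnorm(length(days), 0, 0.3)
  f0 <- fit_growth(data.frame(day = days, weight_kg = w))
  f9 <- fit_growth(data.frame(day = days + 9, weight_kg = w))
  expect_equal(f0$slope, f9$slope, tolerance = 1e-10)
  expect_equal(midtest_weight(f0, 0, 42), midtest_weight(f9, 9, 51),
               tolerance = 1e-10)
  d <- data.frame(day = 0:42, dmi_kg = 2 + rnorm(43, 0, 0.1))
  d9 <- data.frame(day = 0:42 + 9, dmi_kg = d$dmi_kg)
  expect_equal(mean_dmi(d, 0, 42), mean_dmi(d9, 9, 51), tolerance = 1e-10)
})

test_that("noiseless simulated animals yield derived traits equal to truth", {
  G <- simulate_genotypes(30, 100, n_chromosomes = 2, seed = 21)
  sim <- simulate_flock(G, noiseless_config(), seed = 22)
  ph <- derive_phenotypes(sim$weights$p1, sim$intakes$p1, p1_window)
  tr <- sim$truth[match(ph$animal_id, sim$truth$animal_id), ]
  expect_equal(ph$ADG, tr$adg_p1, tolerance = 1e-9)
  expect_equal(ph$MTBW, tr$init_weight_p1 + 21 * tr$adg_p1,
               tolerance = 1e-9)
  # with RFI off, DMI is exactly the model prediction from true traits
  cfg <- noiseless_config()
  expect_equal(ph$DMI,
               cfg$b0[1] + cfg$B1[1] * ph$MBW + cfg$B2 * ph$ADG,
               tolerance = 1e-9)
})

test_that("animals with too few records are excluded with a reason", {
  sim <- small_flock()$sim
  w <- sim$weights$p1
  f <- sim$intakes$p1
  w[[1]] <- w[[1]][1, , drop = FALSE]       # one weighing only
  ph <- derive_phenotypes(w, f, p1_window)
  excl <- attr(ph, "excluded")
  expect_equal(excl$animal_id, names(w)[1])
  expect_match(excl$reason, "weight")
  expect_false(names(w)[1] %in% ph$animal_id)
  # nothing dropped silently
  expect_equal(nrow(ph) + nrow(excl), length(w))
})
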