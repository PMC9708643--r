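test_that("intercept-only NB fit recovers the sample mean exactly", {
  set.seed(1)
  y <- rnbinom(40, size = 2, mu = 30)
  f <- fit_nb_glm(y, matrix(1, 40, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(f$fitted[1]), mean(y), tolerance = 1e-7)
  expect_true(f$converged)
})

test_that("Poisson-simulated data drive the dispersion large and match the Poisson fit", {
  set.seed(21)
  an <- make_animals(c(50, 50, 50, 50))
  X <- fosnet:::factorial_design(an)
  eta <- 3 + 0.4 * X[, "stim"] - 0.3 * X[, "time"]
  y <- rpois(nrow(X), exp(eta))
  f <- fit_nb_glm(y, X)
  pois <- glm.fit(X, y, family = poisson())
  expect_gt(f$theta, 1e3)
  se <- sqrt(diag(f$vcov))
  expect_true(all(abs(f$coefficients - pois$coefficients) < 1e-3))
  expect_true(all(abs(f$coefficients - pois$coefficients) < 3 * se))
})

test_that("NB fit agrees with the glm.nb reference on integer count data", {
  skip_if_not_installed("MASS")
  set.seed(31)
  an <- make_animals(c(30, 30, 30, 30))
  X <- fosnet:::factorial_design(an)
  dat <- data.frame(y = rnbinom(nrow(X), size = 3,
                                mu = exp(3 + 0.5 * X[, "stim"])),
                    stim = X[, "stim"], tim = X[, "time"])
  f <- fit_nb_glm(dat$y, X)
  ref <- MASS::glm.nb(y ~ stim * tim, data = dat)
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(f$theta, ref$theta, tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("planted stimulation effect is recovered within its Wald interval", {
  n <- 200L
  cfg <- synthetic_config(
    n_per_group = c("acute-sham" = n, "acute-active" = n,
                    "chronic-sham" = n, "chronic-active" = n),
    regions = 2L, effect_stim = 0.5, seed = 13)
  sim <- generate_cohort(cfg)
  f <- fit_nb_glm(sim$table$values[, 1],
                  fosnet:::factorial_design(sim$table$animals))
  se <- sqrt(f$vcov["stim", "stim"])
  expect_lt(abs(f$coefficients[["stim"]] - 0.5), 3 * se)
})

test_that("degenerate responses are handled, not crashed on", {
  X <- fosnet:::factorial_design(make_animals(c(3, 3, 3, 3)))
  expect_warning(f <- fit_nb_glm(rep(0, 12), X), "all-zero")
  expect_true(f$degenerate)
  expect_error(fit_nb_glm(rep(2, 12), X[, c(1, 1, 2, 3)]), "rank deficient")
})

test_that("Cook's distance: symmetry, outlier detection, and LOO refit oracle", {
  an <- make_animals(c(3, 3, 3, 3))
  X <- fosnet:::factorial_design(an)

  # identical replicate values in every cell: all distances equal (zero)
  y_flat <- rep(c(10, 20, 15, 25), each = 3)
  f_flat <- fit_nb_glm(y_flat, X)
  d_flat <- cooks.distance(f_flat)
  expect_true(all(abs(d_flat - d_flat[1]) < 1e-8))

  # a single gross outlier is the argmax
  y_out <- c(10, 11, 10, 20, 21, 20, 15, 14, 300, 25, 24, 26)
  f_out <- fit_nb_glm(y_out, X)
  expect_equal(which.max(cooks.distance(f_out)), 9)

  # one-step distance tracks the exact leave-one-out refit distance
  y <- c(10, 12, 11, 20, 18, 22, 15, 14, 18, 22, 21, 19)
  fit <- fit_nb_glm(y, X)
  d1 <- cooks.distance(fit)
  W <- fit$fitted * fit$theta / (fit$fitted + fit$theta)
  info <- crossprod(X, W * X)
  loo <- vapply(seq_along(y), function(i) {
    bi <- nb_refit_fixed_theta(y[-i], X[-i, , drop = FALSE],
                               fit$theta, fit$coefficients)
    db <- fit$coefficients - bi
    drop(t(db) %*% info %*% db) / ncol(X)
  }, numeric(1))
  appreciable <- loo > 0.005
  expect_true(any(appreciable))
  expect_true(all(abs(d1[appreciable] / loo[appreciable] - 1) < 0.10))
  expect_true(all(abs(d1[!appreciable] - loo[!appreciable]) < 1e-3))
})

test_that("BH step-up matches direct enumeration and its boundary cases", {
  # enumerated example: thresholds k/m*q = 0.0125, 0.025, 0.0375, 0.05
  p <- c(0.001, 0.02, 0.03, 0.9)
  expect_equal(bh_fdr(p, 0.05), bh_brute(p, 0.05))
  expect_equal(bh_fdr(p, 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(bh_fdr(rep(0, 5), 0.05)))
  expect_true(bh_fdr(0.05, 0.05))       # single p = q rejected
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  expect_error(bh_fdr(numeric(0), 0.05), "empty")

  set.seed(5)
  for (i in 1:50) {
    pv <- runif(sample(1:20, 1))
    q <- runif(1, 0.01, 0.2)
    expect_equal(bh_fdr(pv, q), bh_brute(pv, q))
    # monotone in q, superset of Bonferroni
    expect_true(all(bh_fdr(pv, q) | !bh_fdr(pv, q / 2)))
    expect_true(all(bh_fdr(pv, q) | !(pv <= q / length(pv))))
  }
})

test_that("percent change and direction banding follow the reporting convention", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(15, 10), 50)
  expect_equal(percent_change(0, 10), -100)
  expect_true(is.na(percent_change(5, 0)))

  expect_equal(direction_band(250, TRUE), "++")
  expect_equal(direction_band(-50, TRUE), "-")
  expect_equal(direction_band(600, FALSE), "n.s.")
  expect_equal(direction_band(c(100, 501, 200, -1), rep(TRUE, 4)),
               c("+", "+++", "+", "-"))
})

test_that("screen of an effect-free region yields a null omnibus result", {
  an <- make_animals(c(6, 6, 5, 5))
  y <- rep(40, 22)
  s <- screen_region(y, an, region = "X")
  expect_gt(s$omnibus_p, 0.9)
  expect_true(all(is.na(s$simple_main_effects)))
  expect_equal(unname(s$direction_band), c("n.s.", "n.s."))
})

test_that("an interaction-only effect is attributed to the right time level", {
  hits <- vapply(1:100, function(s) {
    cfg <- synthetic_config(
      n_per_group = c("acute-sham" = 100, "acute-active" = 100,
                      "chronic-sham" = 100, "chronic-active" = 100),
      regions = 1L, effect_interaction = 1, seed = 300 + s)
    sim <- generate_cohort(cfg)
    sr <- screen_region(sim$table$values[, 1], sim$table$animals, region = "R001")
    isTRUE(sr$interaction_significant) &&
      sr$simple_main_effects[["chronic"]] < 0.05 &&
      sr$simple_main_effects[["acute"]] >= 0.05
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("omnibus p-values are uniform under the null (no influence exclusion)", {
  pv <- unlist(lapply(1:60, function(s) {
    cfg <- synthetic_config(regions = 30L, seed = 5000 + s)
    sim <- generate_cohort(cfg)
    scr <- analyze_brainwide(sim$table,
                             screen_config(cooks_threshold = 1e9))
    scr$summary$omnibus_p
  }))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("regions with planted effects rank top of the brain-wide screen", {
  cfg <- synthetic_config(
    n_per_group = c("acute-sham" = 50, "acute-active" = 50,
                    "chronic-sham" = 50, "chronic-active" = 50),
    regions = 30L, effect_stim = c(rep(1, 10), rep(0, 20)), seed = 77)
  sim <- generate_cohort(cfg)
  scr <- analyze_brainwide(sim$table)
  top10 <- scr$summary$region[order(scr$summary$omnibus_q)][1:10]
  expect_setequal(top10, sprintf("R%03d", 1:10))
})

test_that("a single-region screen equals screen_region plus trivial FDR", {
  cfg <- synthetic_config(regions = 1L, effect_stim = 1.5, seed = 55)
  sim <- generate_cohort(cfg)
  scr <- analyze_brainwide(sim$table)
  direct <- screen_region(sim$table$values[, 1], sim$table$animals,
                          region = sim$table$regions[1])
  expect_equal(scr$summary$omnibus_p, direct$omnibus_p)
  expect_equal(scr$summary$omnibus_q, direct$omnibus_p)  # BH with m = 1
  expect_equal(scr$summary$n_used, direct$n_used)
})

test_that("influence exclusion changes n_used by exactly the number excluded", {
  an <- make_animals(c(6, 6, 5, 5))
  set.seed(8)
  y <- rnbinom(22, size = 5, mu = 50)
  y[4] <- 2000  # gross outlier
  s <- screen_region(y, an, region = "X")
  expect_gte(length(s$excluded_observations), 1)
  expect_equal(s$n_used, 22 - length(s$excluded_observations))
  expect_true("an04" %in% s$excluded_observations)
})
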