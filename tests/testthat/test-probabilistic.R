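test_that("the Anderson-Darling statistic matches the direct formula", {
  x <- c(0.31, 0.45, 0.62, 0.77, 0.91, 1.12, 1.34, 1.61, 2.05, 2.89)
  cdf <- function(q) plnorm(q, 0, 0.6)
  # direct textbook evaluation, written independently of the implementation
  n <- length(x)
  u <- cdf(sort(x))
  a2 <- -n - sum((2 * seq_len(n) - 1) *
                   (log(u) + log(1 - u[n:1]))) / n
  expect_equal(ad_statistic(x, cdf), a2, tolerance = 1e-10)
})

test_that("the AD statistic agrees with the reference normality test", {
  skip_if_not_installed("nortest")
  set.seed(21)
  x <- rnorm(200, 3, 1.5)
  ours <- ad_statistic(x, function(q) pnorm(q, mean(x), sd(x)))
  theirs <- unname(nortest::ad.test(x)$statistic)
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("fitting recovers a lognormal sample's family and parameters", {
  set.seed(5)
  x <- rlnorm(1000, 0, 1)
  f <- fit_concentration(x)
  expect_equal(f$family, "lognormal")
  expect_lt(abs(f$params$meanlog - 0), 0.1)
  expect_lt(abs(f$params$sdlog - 1), 0.1)
  expect_true(all(c("normal", "lognormal", "gamma", "weibull", "uniform",
                    "triangular") %in% f$gof$family))
})

test_that("degenerate and tiny samples are handled explicitly", {
  expect_warning(f <- fit_concentration(c(3, 3, 3, 3)), "point mass")
  expect_equal(f$family, "point_mass")
  expect_equal(f$params$value, 3)
  expect_identical(rconc_fit(f, 5), rep(3, 5))
  expect_error(fit_concentration(2), "at least 2")
  # below 8 samples: empirical fallback
  small <- fit_concentration(c(1, 2, 3, 4, 5))
  expect_equal(small$family, "empirical")
})

test_that("zero inflation is carried as a point mass at zero", {
  set.seed(9)
  x <- c(rep(0, 30), rlnorm(270, -1, 0.8))
  f <- fit_concentration(x, families = "lognormal")
  expect_equal(f$zero_w, 0.1)
  draws <- rconc_fit(f, 20000)
  expect_equal(mean(draws == 0), 0.1, tolerance = 0.15)
})

test_that("point-mass concentrations collapse the simulation onto the deterministic result", {
  fit <- risk_assessment()
  fits <- point_mass_fits(packaged_conc, at = "mean")
  expect_warning(sim <- simulate(fit, nsim = 500, seed = 3, fits = fits),
                 "unstable")
  r <- fit$risks[fit$risks$statistic == "mean" & !is.na(fit$risks$value), ]
  for (i in seq_len(nrow(r))) {
    key <- paste(c(noncancer = "HQ", cancer = "CR", acute = "AR")[[r$kind[i]]],
                 r$route[i], r$chemical[i], sep = "|")
    row <- sim$table[sim$table$target == key, ]
    expect_equal(row$mean, r$value[i], tolerance = 1e-12)
    expect_equal(row$p1, row$p99, tolerance = 1e-12)
  }
})

test_that("simulation is reproducible bit-for-bit under a fixed seed", {
  fit <- risk_assessment()
  s1 <- simulate(fit, nsim = 1500, seed = 42)
  s2 <- simulate(fit, nsim = 1500, seed = 42)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$inputs, s2$inputs)
  expect_equal(s1$nsim, 1500)
  expect_false(identical(simulate(fit, nsim = 1500, seed = 43)$table,
                         s1$table))
})

test_that("exceedance probability behaves as a tail frequency", {
  set.seed(31)
  u <- runif(10000, 0, 2)
  e <- exceedance_probability(u, 1)
  expect_lt(abs(e$exceedance - 0.5), 3 * sqrt(0.25 / 10000))
  expect_equal(e$certainty, 1 - e$exceedance)
  expect_equal(exceedance_probability(u, Inf)$exceedance, 0)
  expect_equal(exceedance_probability(u + 3, 1)$exceedance, 1)
  # monotone non-increasing in the threshold
  ths <- c(0.2, 0.8, 1.4, 1.9)
  es <- vapply(ths, function(t) exceedance_probability(u, t)$exceedance,
               numeric(1))
  expect_true(all(diff(es) <= 0))
})

test_that("percentile vectors are monotone and thresholds kind-specific", {
  fit <- risk_assessment()
  sim <- simulate(fit, nsim = 2000, seed = 8)
  pc <- as.matrix(sim$table[c("p1", "p5", "p25", "p50", "p75", "p95", "p99")])
  expect_true(all(t(apply(pc, 1L, diff)) >= 0))
  expect_true(all(sim$table$threshold[grepl("^CR", sim$table$target)] ==
                    1e-6))
  expect_true(all(sim$table$threshold[grepl("^(HQ|HI|AR)", sim$table$target)]
                  == 1))
})

test_that("Monte Carlo means converge to potency times the distribution mean", {
  fit <- risk_assessment()
  sim <- simulate(fit, nsim = 10000, seed = 12)
  # cancer risk is linear in concentration: E[CR] = CPV * dose(E[conc])
  row <- packaged_conc[packaged_conc$chemical == "Cr" &
                         packaged_conc$matrix == "aerosol", ]
  expected <- cancer_risk(dose_inhalation(row$mean), 510)
  draws <- sim$outputs[["CR|inhalation|Cr"]]
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("sensitivity attributes all variance to the only varying input", {
  n <- 2000
  set.seed(2)
  x <- rlnorm(n, 0, 1)
  inputs <- cbind(`x|aerosol` = x, `const|aerosol` = rep(2, n))
  sim <- structure(list(outputs = list(`HQ|inhalation|x` = 3 * x),
                        inputs = inputs, nsim = n, seed = 2),
                   class = "risk_simulation")
  s <- sensitivity(sim, "HQ|inhalation|x")
  expect_equal(s$contribution_pct[s$variable == "x|aerosol"], 100)
  expect_equal(s$contribution_pct[s$variable == "const|aerosol"], 0)
  expect_equal(sum(s$contribution_pct), 100, tolerance = 0.1)
})

test_that("a constant output yields all-zero contributions with a warning", {
  n <- 1200
  sim <- structure(list(outputs = list(`HI|oral` = rep(1, n)),
                        inputs = cbind(`a|x` = runif(n)), nsim = n, seed = 1),
                   class = "risk_simulation")
  expect_warning(s <- sensitivity(sim, "HI|oral"), "constant")
  expect_true(all(s$contribution_pct == 0))
})

test_that("missing fitted distributions are a hard error", {
  fit <- risk_assessment()
  fits <- point_mass_fits(packaged_conc)
  fits[["Cr|aerosol"]] <- NULL
  expect_error(suppressWarnings(
    simulate(fit, nsim = 1000, seed = 1, fits = fits)),
    "no fitted distribution.*Cr")
})
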