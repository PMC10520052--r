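test_that("harmonize expands each report kind correctly", {
  s <- harmonize(sample_records())
  # range_only -> two samples at the published extremes
  a1 <- s$value[s$study_id == "a1"]
  expect_equal(sort(a1), c(0, 28.1))
  # per-power series -> a single averaged sample
  expect_equal(s$value[s$study_id == "a2"], 0.4)
  # individual with unit conversion ng -> ug
  expect_equal(s$value[s$study_id == "a3"], 0.15)
  # e-liquid ug/ml -> mg/ml
  expect_equal(s$value[s$study_id == "b1"], 0.0758)
  # study count is preserved
  expect_equal(length(unique(s$study_id)), 4L)
})

test_that("harmonize rejects bad units and negative values", {
  rec <- data.frame(chemical = "Cu", matrix = "aerosol", value = 1,
                    unit = "mol/l", study_id = "x", report_kind = "individual")
  expect_error(harmonize(rec), "unsupported unit")
  rec$unit <- "ug/puff"
  rec$value <- -1
  expect_error(harmonize(rec), "non-negative")
})

test_that("unit conversion round-trips to relative error below 1e-12", {
  x <- c(1e-6, 0.37, 28.1, 912)
  for (u in c("ng/puff", "mg/puff")) {
    fwd <- convert_concentration(x, u, "aerosol")
    fac <- convert_concentration(1, u, "aerosol")
    expect_equal(fwd / fac, x, tolerance = 1e-12)
  }
  fwd <- convert_concentration(x, "ug/ml", "e-liquid")
  expect_equal(fwd * 1e3, x, tolerance = 1e-12)
})

test_that("summaries compute mean, n-1 sd, range and study counts", {
  s <- data.frame(chemical = "Cu", matrix = "aerosol", value = c(1, 2, 3),
                  study_id = c("s1", "s2", "s2"))
  out <- summarize_concentrations(s)
  expect_equal(out$mean, 2)
  expect_equal(out$sd, 1)
  expect_equal(out$min, 1)
  expect_equal(out$max, 3)
  expect_equal(out$n_refs, 2L)
  # single sample: sd 0 by convention
  one <- summarize_concentrations(
    data.frame(chemical = "Cu", matrix = "aerosol", value = 5,
               study_id = "s1"))
  expect_equal(one$sd, 0)
  expect_equal(one$mean, 5)
  expect_error(summarize_concentrations(one[0, c(1, 2, 3, 7)]), "no samples")
})

test_that("summarize(harmonize(x)) is invariant to record order", {
  rec <- sample_records()
  s1 <- summarize_concentrations(harmonize(rec))
  s2 <- summarize_concentrations(harmonize(rec[rev(seq_len(nrow(rec))), ]))
  expect_equal(s1, s2)
})

test_that("sample means of a known lognormal approach the analytic mean", {
  set.seed(11)
  mu <- 0; sigma <- 1; n <- 1000
  x <- rlnorm(n, mu, sigma)
  s <- data.frame(chemical = "Ni", matrix = "aerosol", value = x,
                  study_id = paste0("s", seq_len(n)))
  out <- summarize_concentrations(s)
  m_true <- exp(mu + sigma^2 / 2)                  # analytic moments
  sd_true <- sqrt((exp(sigma^2) - 1) * exp(2 * mu + sigma^2))
  expect_lt(abs(out$mean - m_true), 3 * sd_true / sqrt(n))
})

test_that("packaged summaries match the compiled tables and are coherent", {
  d <- packaged_conc
  expect_equal(nrow(d), 22L)
  f <- d[d$chemical == "formaldehyde" & d$matrix == "aerosol", ]
  expect_equal(f$mean, 0.864)
  expect_equal(f$sd, 3.32)
  expect_equal(c(f$min, f$max), c(0, 28.1))
  expect_equal(f$n_refs, 12L)
  cu <- d[d$chemical == "Cu" & d$matrix == "e-liquid", ]
  expect_equal(cu$mean, 0.105)
  expect_equal(cu$max, 0.927)
  # internally consistent acetone/acrolein assignment
  expect_equal(d$mean[d$chemical == "acrolein" & d$matrix == "aerosol"],
               0.373)
  expect_equal(d$mean[d$chemical == "acetone" & d$matrix == "aerosol"],
               0.242)
  expect_true(all(d$min <= d$mean & d$mean <= d$max))
  expect_true(all(d$sd >= 0))
})

test_that("the as-printed variant is available but warns", {
  expect_warning(p <- packaged_summaries("as_printed"), "transposed")
  expect_equal(p$mean[p$chemical == "acetone" & p$matrix == "aerosol"], 0.373)
  expect_equal(p$mean[p$chemical == "acrolein" & p$matrix == "aerosol"],
               0.242)
})

test_that("surrogate samples reproduce the summary's first two moments", {
  row <- packaged_conc[packaged_conc$chemical == "Cu" &
                         packaged_conc$matrix == "e-liquid", ]
  x <- surrogate_samples(row, n = 2000)
  expect_true(all(x >= row$min & x <= row$max))
  expect_equal(mean(x), row$mean, tolerance = 0.15)
})
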