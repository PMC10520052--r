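# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rfamily <- function(n, family, params) {
  p <- params
  switch(family,
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    normal = pmax(stats::rnorm(n, p$mean, p$sd), 0),
    gamma = stats::rgamma(n, p$shape, p$rate),
    weibull = stats::rweibull(n, p$shape, p$scale),
    uniform = stats::runif(n, p$min, p$max),
    triangular = rtri(n, p$min, p$max, p$mode),
    stop("unsupported ground-truth family ", family, call. = FALSE)
  )
}

#' Configure a synthetic literature study set
#'
#' Describes a ground-truth concentration distribution and how a body of
#' literature would report draws from it: how many independent studies, what
#' fraction of measurements are non-detects (reported as 0), and the mix of
#' reporting styles (individual values, a published mean only, a published
#' range only, or a per-power-level series that gets averaged).
#'
#' @param chemical Chemical id.
#' @param matrix `"aerosol"` or `"e-liquid"`.
#' @param family Ground-truth family (default `"lognormal"`: concentrations
#'   are non-negative and right-skewed, with SD exceeding the mean for most
#'   compiled chemicals).
#' @param params Named list of family parameters.
#' @param n_studies Number of source studies, `>= 1`.
#' @param zero_fraction Proportion of non-detect measurements in `[0, 1)`
#'   (or exactly 1 for an all-non-detect set).
#' @param report_kind_mix Named proportions over
#'   `c("individual", "mean_only", "range_only", "per_power_series")`,
#'   summing to 1.
#' @param values_per_study Measurements underlying an individual or
#'   mean-only study (default 3).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A list of class `generator_config`.
#' @export
synthetic_config <- function(chemical, matrix, family = "lognormal",
                             params = list(meanlog = 0, sdlog = 1),
                             n_studies = 10, zero_fraction = 0,
                             report_kind_mix = c(individual = 1,
                                                 mean_only = 0,
                                                 range_only = 0,
                                                 per_power_series = 0),
                             values_per_study = 3, seed = 1) {
  assert_chemical(chemical)
  matrix <- match.arg(matrix, c("aerosol", "e-liquid"))
  kinds <- c("individual", "mean_only", "range_only", "per_power_series")
  if (!setequal(names(report_kind_mix), kinds) ||
      abs(sum(report_kind_mix) - 1) > 1e-8 || any(report_kind_mix < 0)) {
    stop("report_kind_mix must be non-negative proportions over ",
         paste(kinds, collapse = "/"), " summing to 1", call. = FALSE)
  }
  if (n_studies < 1) stop("n_studies must be >= 1", call. = FALSE)
  if (zero_fraction < 0 || zero_fraction > 1) {
    stop("zero_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(chemical = chemical, matrix = matrix, family = family,
                 params = params, n_studies = n_studies,
                 zero_fraction = zero_fraction,
                 report_kind_mix = report_kind_mix[kinds],
                 values_per_study = values_per_study, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic literature study set
#'
#' Draws true concentrations from the configured ground-truth distribution,
#' replaces a `zero_fraction` of them by non-detect zeros, and packages them
#' into raw literature records according to the reporting mix:
#' `individual` studies report each of their measurements, `mean_only`
#' studies report the mean of their measurements, `range_only` studies report
#' the minimum and maximum of a batch of 5, and `per_power_series` studies
#' report 3 within-study power-level replicates (which [harmonize()] then
#' averages). Deterministic for a given config and seed.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_study_set` with `records` (a data
#'   frame in the sample CSV dialect: `chemical`, `matrix`, `value`, `unit`,
#'   `study_id`, `report_kind`), the `truth` config, and the `seed`.
#' @export
#' @examples
#' cfg <- synthetic_config("Cr", "aerosol",
#'                         params = list(meanlog = -8, sdlog = 1),
#'                         n_studies = 5, seed = 42)
#' generate_studies(cfg)$records
generate_studies <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  unit <- if (config$matrix == "aerosol") "ug/puff" else "mg/ml"
  records <- with_seed(config$seed, {
    kinds <- sample(names(config$report_kind_mix), config$n_studies,
                    replace = TRUE, prob = config$report_kind_mix)
    out <- vector("list", config$n_studies)
    for (i in seq_len(config$n_studies)) {
      kind <- kinds[i]
      n_true <- switch(kind,
        individual = config$values_per_study,
        mean_only = config$values_per_study,
        range_only = 5L, # fixed batch size before taking min/max
        per_power_series = 3L)
      x <- rfamily(n_true, config$family, config$params)
      x[stats::runif(n_true) < config$zero_fraction] <- 0
      reported <- switch(kind,
        individual = x,
        mean_only = mean(x),
        range_only = range(x),
        per_power_series = x)
      out[[i]] <- data.frame(
        chemical = config$chemical, matrix = config$matrix,
        value = reported, unit = unit,
        study_id = sprintf("%s_%s_s%03d", config$chemical,
                           sub("-", "", config$matrix), i),
        report_kind = kind, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rownames(records) <- NULL
  structure(list(records = records, truth = config, seed = config$seed),
            class = "synthetic_study_set")
}

#' Generate a full two-matrix literature-like dataset
#'
#' Emits synthetic raw records for all eleven chemicals in both matrices,
#' with lognormal ground truth moment-matched to the packaged summary means
#' and SDs and study counts equal to the packaged numbers of references, so
#' that end-to-end runs (harmonize, summarize, fit, assess, simulate)
#' produce risk tables of the reference order of magnitude. The reporting
#' mix is 50% individual, 20% mean-only, 20% range-only, 10% per-power
#' series; chemicals whose compiled range touches zero get a 2% non-detect
#' rate (non-detects occur in the compiled literature but are uncommon).
#'
#' @param seed Integer seed.
#' @param variant Summary variant passed to [packaged_summaries()].
#' @return A list with `records` (all raw records, sample CSV dialect) and
#'   `truth` (the per-chemical/matrix [synthetic_config()] list).
#' @export
#' @examples
#' ds <- generate_paper_like_study(seed = 1)
#' head(ds$records)
generate_paper_like_study <- function(seed = 1, variant = "as_used") {
  summ <- packaged_summaries(variant)
  mix <- c(individual = 0.5, mean_only = 0.2, range_only = 0.2,
           per_power_series = 0.1)
  configs <- list()
  records <- list()
  for (i in seq_len(nrow(summ))) {
    row <- summ[i, , drop = FALSE]
    if (row$mean <= 0 || row$sd <= 0) next
    par <- moment_lognormal(row$mean, row$sd)
    cfg <- synthetic_config(
      chemical = row$chemical, matrix = row$matrix, family = "lognormal",
      params = par, n_studies = row$n_refs,
      zero_fraction = if (row$min == 0) 0.02 else 0,
      report_kind_mix = mix, values_per_study = 3,
      seed = (seed * 1009L + i) %% .Machine$integer.max)
    key <- paste(row$chemical, row$matrix, sep = "|")
    configs[[key]] <- cfg
    records[[key]] <- generate_studies(cfg)$records
  }
  list(records = do.call(rbind, c(records, list(make.row.names = FALSE))),
       truth = configs, seed = seed)
}
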