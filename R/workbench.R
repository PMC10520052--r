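#' Run the full assessment workbench
#'
#' Orchestrates the pipeline end to end (load or generate concentrations,
#' compute exposures and risks, aggregate, optionally simulate) and writes a
#' report bundle: per-route dose, cancer, hazard-quotient and acute tables as
#' CSV (values in scientific notation with 3 significant digits), route
#' totals, a full-precision `results.json`, and — in probabilistic mode —
#' percentile, exceedance and sensitivity tables plus the fitted
#' distributions. A `manifest.json` records the package version, seed, mode
#' and an MD5 digest of every file input, so identical configurations
#' reproduce byte-identical bundles.
#'
#' @param config A list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{data}{`list(source = "packaged")` (default),
#'       `list(source = "samples", path = <csv>)` for sample-level data in
#'       the dialect `chemical,matrix,value,unit,study_id,report_kind`, or
#'       `list(source = "synthetic", seed = <int>)`;}
#'     \item{scenario}{path to a scenario file, or `NULL` for the default;}
#'     \item{mode}{`"deterministic"` (default), `"worst-case"` or
#'       `"probabilistic"`;}
#'     \item{dermal_mode}{`"paper_replication"` (default) or `"as_stated"`;}
#'     \item{n_iter}{Monte Carlo iterations (default 10000);}
#'     \item{seed}{integer seed (default 1);}
#'     \item{out_dir}{output directory (created if absent).}
#'   }
#' @return Invisibly, a list with the `risk_assessment` object, the
#'   simulation (or `NULL`) and the paths written.
#' @export
run_workbench <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = ,
      yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      stop("unsupported config format: .", ext, call. = FALSE))
  }
  data_cfg <- config$data %||% list(source = "packaged")
  mode <- config$mode %||% "deterministic"
  mode <- match.arg(mode, c("deterministic", "worst-case", "probabilistic"))
  dermal_mode <- config$dermal_mode %||% "paper_replication"
  n_iter <- config$n_iter %||% 10000
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  scenario <- if (is.null(config$scenario)) exposure_scenario()
              else read_scenario(config$scenario)
  input_digests <- list()
  samples <- NULL
  if (data_cfg$source == "packaged") {
    summaries <- packaged_summaries()
  } else if (data_cfg$source == "samples") {
    input_digests[[data_cfg$path]] <-
      unname(tools::md5sum(data_cfg$path))
    raw <- utils::read.csv(data_cfg$path, stringsAsFactors = FALSE)
    samples <- harmonize(raw)
    summaries <- if (nrow(samples)) {
      summarize_concentrations(samples)
    } else {
      data.frame(chemical = character(), matrix = character(),
                 mean = numeric(), sd = numeric(), min = numeric(),
                 max = numeric(), n_refs = integer(),
                 stringsAsFactors = FALSE)
    }
  } else if (data_cfg$source == "synthetic") {
    ds <- generate_paper_like_study(seed = data_cfg$seed %||% seed)
    samples <- harmonize(ds$records)
    summaries <- summarize_concentrations(samples)
  } else {
    stop("unknown data source '", data_cfg$source, "'", call. = FALSE)
  }
  if (nrow(summaries) == 0L) {
    warning("no chemicals in input; writing empty tables", call. = FALSE)
  }

  fit <- risk_assessment(summaries, scenario = scenario,
                         dermal_mode = dermal_mode)
  sm <- summary(fit)
  paths <- character()
  wr <- function(d, name, sci_cols = intersect(c("min", "mean", "max"),
                                               names(d))) {
    for (col in sci_cols) d[[col]] <- fmt3(d[[col]])
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE, na = "-")
    paths <<- c(paths, p)
  }
  statistic_shown <- if (mode == "worst-case") "max" else "mean"
  wr(sm$doses, "exposure.csv")
  wr(sm$cancer, "cancer_risk.csv")
  wr(sm$hq, "hazard_quotient.csv")
  wr(sm$acute, "acute_risk.csv")
  tot <- fit$totals[fit$totals$statistic == statistic_shown, , drop = FALSE]
  wr(tot, "totals.csv", sci_cols = "total")
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    list(doses = fit$doses, risks = fit$risks, totals = fit$totals),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, json_path)

  sim <- NULL
  if (mode == "probabilistic") {
    fits <- if (is.null(samples)) {
      summary_fits(summaries)
    } else {
      keys <- unique(paste(samples$chemical, samples$matrix, sep = "|"))
      out <- lapply(keys, function(k) {
        parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
        v <- samples$value[samples$chemical == parts[1L] &
                             samples$matrix == parts[2L]]
        fit_concentration(v, variable = k)
      })
      names(out) <- keys
      out
    }
    sim <- simulate(fit, nsim = n_iter, seed = seed, fits = fits)
    wr(sim$table, "percentiles.csv",
       sci_cols = c("mean", "p1", "p5", "p25", "p50", "p75", "p95", "p99"))
    exc <- sim$table[grepl("^HQ\\|", sim$table$target), , drop = FALSE]
    exc <- data.frame(target = exc$target,
                      certainty_pct = sprintf("%.2f", exc$certainty_pct),
                      exceedance_pct = sprintf("%.2f", exc$exceedance_pct))
    wr(exc, "exceedance.csv", sci_cols = character())
    sens <- do.call(rbind, lapply(
      intersect(c("HI|inhalation", "CR_total|inhalation",
                  "CR_total|dermal", "CR_total|oral"),
                names(sim$outputs)),
      function(tg) {
        s <- sensitivity(sim, tg)
        data.frame(target = tg, as.data.frame(s))
      }))
    wr(sens, "sensitivity.csv", sci_cols = character())
    fit_json <- file.path(out_dir, "fits.json")
    jsonlite::write_json(
      lapply(fits, function(f) {
        list(variable = f$variable, family = f$family, params = f$params,
             zero_w = f$zero_w, n = f$n, gof = f$gof)
      }),
      fit_json, auto_unbox = TRUE, digits = NA, na = "null")
    paths <- c(paths, fit_json)
  }

  manifest <- list(
    package = "vaporisk",
    version = as.character(utils::packageVersion("vaporisk")),
    mode = mode, dermal_mode = dermal_mode, seed = seed,
    n_iter = if (mode == "probabilistic") n_iter else NULL,
    data_source = data_cfg$source,
    input_digests = input_digests,
    files = basename(paths))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  paths <- c(paths, manifest_path)
  invisible(list(assessment = fit, simulation = sim, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recompute the reference results from the packaged inputs
#'
#' Runs the deterministic pipeline on the packaged concentration summaries
#' and toxicity tables and compares a panel of benchmark quantities with the
#' values reported for them (mean inhalation doses, cancer risks and hazard
#' quotients, the inhalation hazard index, acute risks and the dermal
#' arsenic cancer risk). Agreement within 1% relative tolerance absorbs the
#' rounding of the reported intermediate values.
#'
#' @param tolerance Relative tolerance for the `pass` flag (default 0.01).
#' @return A data frame with one row per benchmark: `id`, `description`,
#'   `computed`, `reported`, `rel_err`, `pass`.
#' @export
#' @examples
#' validate_paper()
validate_paper <- function(tolerance = 0.01) {
  fit <- risk_assessment()
  r <- fit$risks
  d <- fit$doses
  pick_risk <- function(kind, route, chem) {
    r$value[r$kind == kind & r$route == route & r$chemical == chem &
              r$statistic == "mean"]
  }
  hi <- fit$totals
  computed <- c(
    t1 = d$value[d$chemical == "formaldehyde" & d$route == "inhalation" &
                   d$statistic == "mean"],
    t2 = pick_risk("cancer", "inhalation", "Cr"),
    t3 = pick_risk("cancer", "inhalation", "formaldehyde"),
    t4 = pick_risk("cancer", "inhalation", "Ni"),
    t5 = pick_risk("cancer", "inhalation", "As"),
    t6 = pick_risk("noncancer", "inhalation", "acrolein"),
    t7 = pick_risk("noncancer", "inhalation", "Ni"),
    t8 = pick_risk("noncancer", "inhalation", "formaldehyde"),
    t9 = hi$total[hi$statistic == "mean" & hi$kind == "noncancer" &
                    hi$route == "inhalation"],
    t10 = pick_risk("acute", "oral", "formaldehyde"),
    t11 = pick_risk("acute", "dermal", "As"),
    t12 = pick_risk("cancer", "dermal", "As")
  )
  reported <- c(t1 = 2.01e-3, t2 = 4.39e-4, t3 = 4.22e-5, t4 = 3.11e-5,
                t5 = 6.74e-6, t6 = 151.97, t7 = 8.55, t8 = 0.78,
                t9 = 170.63, t10 = 9.65e-7, t11 = 2.68e-8, t12 = 2.43e-6)
  description <- c(
    t1 = "mean chronic inhalation dose, formaldehyde (mg/kg day)",
    t2 = "mean inhalation cancer risk, Cr",
    t3 = "mean inhalation cancer risk, formaldehyde",
    t4 = "mean inhalation cancer risk, Ni",
    t5 = "mean inhalation cancer risk, As",
    t6 = "mean inhalation hazard quotient, acrolein",
    t7 = "mean inhalation hazard quotient, Ni",
    t8 = "mean inhalation hazard quotient, formaldehyde",
    t9 = "inhalation hazard index (sum of assessed HQs)",
    t10 = "mean oral acute risk, formaldehyde",
    t11 = "mean dermal acute risk, As",
    t12 = "mean dermal cancer risk, As (paper-replication mode)")
  rel_err <- abs(computed - reported) / abs(reported)
  data.frame(id = names(computed), description = unname(description),
             computed = unname(computed), reported = unname(reported),
             rel_err = unname(rel_err), pass = unname(rel_err <= tolerance),
             stringsAsFactors = FALSE)
}
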