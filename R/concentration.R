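#' @keywords internal
#' @name concentration-units
#' @noRd
NULL

# canonical units: aerosol ug/puff, e-liquid mg/ml
UNIT_FACTORS <- list(
  aerosol = c("ug/puff" = 1, "ng/puff" = 1e-3, "mg/puff" = 1e3),
  `e-liquid` = c("mg/ml" = 1, "ug/ml" = 1e-3, "mg/g" = 1) # density 1 g/ml
)

#' Convert a concentration to the canonical unit of its matrix
#'
#' Aerosol concentrations are expressed per puff (canonical ug/puff);
#' e-liquid concentrations per volume (canonical mg/ml, with mg/g converted
#' at an assumed density of 1 g/ml).
#'
#' @param value Numeric vector of concentrations, `>= 0`.
#' @param unit Source unit: one of `"ug/puff"`, `"ng/puff"`, `"mg/puff"`
#'   (aerosol) or `"mg/ml"`, `"ug/ml"`, `"mg/g"` (e-liquid).
#' @param matrix `"aerosol"` or `"e-liquid"`.
#' @return Numeric vector in canonical units.
#' @export
convert_concentration <- function(value, unit, matrix) {
  matrix <- match.arg(matrix, c("aerosol", "e-liquid"))
  fac <- UNIT_FACTORS[[matrix]]
  if (!unit %in% names(fac)) {
    stop("unsupported unit '", unit, "' for matrix ", matrix, call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  value * unname(fac[unit])
}

#' Harmonize raw literature concentration records into samples
#'
#' Source articles report concentrations in heterogeneous ways; each reported
#' record becomes one or more harmonized samples:
#' \describe{
#'   \item{individual}{every reported value is one sample;}
#'   \item{mean_only}{the published mean counts as the result of one sample;}
#'   \item{range_only}{the published minimum and maximum count as the results
#'     of two samples;}
#'   \item{per_power_series}{results at different device power levels are
#'     averaged into a single sample for that study.}
#' }
#' All values are converted to canonical units (aerosol ug/puff, e-liquid
#' mg/ml). Non-detects are encoded as value 0.
#'
#' @param records A data frame with columns `chemical`, `matrix`, `value`,
#'   `unit`, `study_id`, `report_kind` — one row per reported value; rows of
#'   one record share `(study_id, chemical, matrix)`.
#' @return A data frame of harmonized samples with columns `chemical`,
#'   `matrix`, `value` (canonical units) and `study_id`.
#' @export
#' @examples
#' rec <- data.frame(chemical = "formaldehyde", matrix = "aerosol",
#'                   value = c(0, 28.1), unit = "ug/puff",
#'                   study_id = "s1", report_kind = "range_only")
#' harmonize(rec)
harmonize <- function(records) {
  needed <- c("chemical", "matrix", "value", "unit", "study_id", "report_kind")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    return(data.frame(chemical = character(), matrix = character(),
                      value = numeric(), study_id = character(),
                      stringsAsFactors = FALSE))
  }
  assert_chemical(unique(records$chemical))
  if (any(records$value < 0, na.rm = TRUE) || any(!is.finite(records$value))) {
    stop("concentration values must be finite and non-negative", call. = FALSE)
  }
  key <- interaction(records$study_id, records$chemical, records$matrix,
                     records$report_kind, drop = TRUE)
  out <- lapply(split(records, key), function(d) {
    kind <- d$report_kind[1L]
    vals <- convert_concentration(d$value, d$unit[1L], d$matrix[1L])
    samp <- switch(kind,
      individual = vals,
      mean_only = {
        if (nrow(d) != 1L) stop("mean_only record must have exactly 1 value",
                                call. = FALSE)
        vals
      },
      range_only = {
        if (nrow(d) != 2L) stop("range_only record must have exactly 2 values",
                                call. = FALSE)
        if (min(vals) > max(vals)) stop("range_only min > max", call. = FALSE)
        c(min(vals), max(vals))
      },
      per_power_series = mean(vals),
      stop("unknown report_kind '", kind, "'", call. = FALSE)
    )
    data.frame(chemical = d$chemical[1L], matrix = d$matrix[1L],
               value = samp, study_id = d$study_id[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize harmonized concentration samples
#'
#' Computes, per chemical and matrix, the mean, sample (n-1) standard
#' deviation, minimum, maximum and the number of distinct source studies.
#' A single-sample group has `sd = 0` by convention, so every summary is
#' well defined.
#'
#' @param samples A data frame as returned by [harmonize()].
#' @return A data frame with columns `chemical`, `matrix`, `mean`, `sd`,
#'   `min`, `max`, `n_refs`.
#' @export
summarize_concentrations <- function(samples) {
  if (nrow(samples) == 0L) {
    stop("no samples to summarize", call. = FALSE)
  }
  key <- interaction(samples$chemical, samples$matrix, drop = TRUE)
  out <- lapply(split(samples, key), function(d) {
    s <- if (nrow(d) > 1L) stats::sd(d$value) else 0
    data.frame(chemical = d$chemical[1L], matrix = d$matrix[1L],
               mean = mean(d$value), sd = s,
               min = min(d$value), max = max(d$value),
               n_refs = length(unique(d$study_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$chemical, chemical_ids()), out$matrix), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged concentration summaries for aerosols and e-liquids
#'
#' Returns the compiled per-chemical concentration summaries (mean, SD, range
#' and number of source articles) for the eleven study chemicals in both
#' matrices: aerosol in ug/puff, e-liquid in mg/ml.
#'
#' Two variants are packaged. In the source compilation the aerosol rows for
#' acetone and acrolein are internally transposed: every downstream dose and
#' risk value is consistent with acrolein = 0.373 ug/puff and acetone =
#' 0.242 ug/puff, the opposite of the summary table as printed. The default
#' `"as_used"` variant adopts the internally consistent assignment;
#' `"as_printed"` returns the rows exactly as printed (with a warning), so
#' both remain inspectable.
#'
#' @param variant `"as_used"` (default) or `"as_printed"`.
#' @return A data frame with columns `chemical`, `matrix`, `mean`, `sd`,
#'   `min`, `max`, `n_refs`.
#' @export
#' @examples
#' head(packaged_summaries())
packaged_summaries <- function(variant = c("as_used", "as_printed")) {
  variant <- match.arg(variant)
  files <- system.file("extdata", "tables",
                       c("aerosol_summary.csv", "eliquid_summary.csv"),
                       package = "vaporisk", mustWork = TRUE)
  d <- do.call(rbind, lapply(files, utils::read.csv,
                             stringsAsFactors = FALSE))
  if (variant == "as_printed") {
    warning("as_printed summaries requested: the aerosol acetone/acrolein ",
            "rows are transposed relative to the values used downstream",
            call. = FALSE)
    d$mean <- d$mean_printed
    d$sd <- d$sd_printed
    d$min <- d$min_printed
    d$max <- d$max_printed
    d$n_refs <- d$n_refs_printed
  }
  d <- d[c("chemical", "matrix", "mean", "sd", "min", "max", "n_refs")]
  stopifnot(all(d$min <= d$mean), all(d$mean <= d$max), all(d$sd >= 0))
  d
}

#' Build a surrogate sample set from a concentration summary
#'
#' The source compilation publishes only per-chemical summaries (mean, SD,
#' range), not the underlying sample values. For distribution fitting a
#' surrogate sample set can be constructed from a summary row: a lognormal is
#' moment-matched to the mean and SD, `n` values are taken at equally spaced
#' quantiles, and clipped to the published range. This construction is a
#' package convenience, not part of the source methodology; fitted
#' distributions from surrogates inherit only the summary's first two moments.
#'
#' @param summary_row One row of [packaged_summaries()].
#' @param n Number of surrogate samples (default 200).
#' @return Numeric vector of `n` surrogate concentrations.
#' @export
surrogate_samples <- function(summary_row, n = 200) {
  stopifnot(nrow(summary_row) == 1L, n >= 2L)
  m <- summary_row$mean
  s <- summary_row$sd
  if (m <= 0 || s <= 0) {
    return(rep(m, n))
  }
  par <- moment_lognormal(m, s)
  p <- (seq_len(n) - 0.5) / n
  x <- stats::qlnorm(p, par$meanlog, par$sdlog)
  pmin(pmax(x, summary_row$min), summary_row$max)
}

#' Moment-match a lognormal to a mean and standard deviation
#'
#' Solves for `(meanlog, sdlog)` such that the lognormal has the given
#' arithmetic mean and SD: `sdlog^2 = log(1 + (s/m)^2)`,
#' `meanlog = log(m) - sdlog^2 / 2`.
#'
#' @param m Arithmetic mean, `> 0`.
#' @param s Arithmetic standard deviation, `> 0`.
#' @return A list with `meanlog` and `sdlog`.
#' @export
moment_lognormal <- function(m, s) {
  stopifnot(m > 0, s > 0)
  s2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}
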