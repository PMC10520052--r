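#' Incremental lifetime cancer risk from a chronic dose
#'
#' `CR = potency * dose`, with the cancer potency value (inhalation) or slope
#' factor (oral/dermal) in (mg/kg day)^-1. A missing potency (`NA`) yields
#' `NA`: the assessment is not performed, which is distinct from zero risk.
#'
#' @param dose Chronic daily dose, mg/kg day (vectorized).
#' @param potency Cancer potency value / slope factor, (mg/kg day)^-1.
#' @return Unitless incremental lifetime cancer risk; acceptable when
#'   `<= 1e-6`.
#' @export
#' @examples
#' cancer_risk(8.62e-7, 510) # chromium, inhalation
cancer_risk <- function(dose, potency) {
  if (any(potency <= 0, na.rm = TRUE)) {
    stop("cancer potency must be positive", call. = FALSE)
  }
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("doses must be finite and non-negative", call. = FALSE)
  }
  potency * dose
}

#' Hazard quotient of a chronic dose
#'
#' `HQ = dose / reference`, the ratio of the chronic daily dose to the
#' non-cancer reference dose for that chemical and route. `HQ <= 1` is
#' acceptable, `HQ > 1` signals a possible adverse effect, `HQ > 10` a high
#' non-cancer risk. A missing reference (`NA`) yields `NA` (not assessed).
#'
#' @param dose Chronic daily dose, mg/kg day (vectorized).
#' @param reference Reference dose, mg/kg day, or a [noncancer_reference_dose()]
#'   result.
#' @return Unitless hazard quotient.
#' @export
#' @examples
#' hazard_quotient(8.69e-4, 5.714e-6) # acrolein, inhalation
hazard_quotient <- function(dose, reference) {
  if (inherits(reference, "reference_dose")) reference <- reference$value
  if (any(reference <= 0, na.rm = TRUE)) {
    stop("reference dose must be positive", call. = FALSE)
  }
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("doses must be finite and non-negative", call. = FALSE)
  }
  dose / reference
}

#' Acute risk ratio of an acute intake
#'
#' `AR = I / LD50`: the one-off intake relative to the route-specific median
#' lethal dose. `AR > 1` is unacceptable. A missing LD50 yields `NA`.
#'
#' @param intake Acute intake, mg/kg (vectorized).
#' @param ld50 Median lethal dose for the route, mg/kg.
#' @return Unitless acute risk ratio.
#' @export
acute_risk <- function(intake, ld50) {
  if (any(ld50 <= 0, na.rm = TRUE)) {
    stop("LD50 must be positive", call. = FALSE)
  }
  if (any(!is.finite(intake)) || any(intake < 0)) {
    stop("intakes must be finite and non-negative", call. = FALSE)
  }
  intake / ld50
}

risk_threshold <- function(kind) {
  c(cancer = 1e-6, noncancer = 1, acute = 1)[[kind]]
}

#' Fit the multi-route risk assessment
#'
#' The central constructor: evaluates the full deterministic pipeline from
#' concentration summaries to per-chemical, per-route risks. For every
#' chemical with an aerosol summary the chronic inhalation dose is computed
#' ([dose_inhalation()]); for every chemical with an e-liquid summary the
#' chronic oral and dermal doses and the acute intake are computed. Doses are
#' evaluated at the minimum, mean and maximum concentration of each summary,
#' then converted to cancer risks ([cancer_risk()]), hazard quotients
#' ([hazard_quotient()], with the minimum-reference rule of
#' [noncancer_reference_dose()]) and acute risk ratios ([acute_risk()]).
#' Chemicals without a reference value for a route are flagged "not assessed"
#' and excluded from totals; totals sum independent risks with no
#' interaction terms.
#'
#' @param summaries Concentration summaries as from [packaged_summaries()]
#'   or [summarize_concentrations()].
#' @param refs Toxicity references from [load_toxicity_refs()].
#' @param scenario An [exposure_scenario()].
#' @param dermal_mode Dermal absorption mode, see [dose_dermal()].
#' @return An object of class `risk_assessment` with components
#'   \describe{
#'     \item{doses}{per chemical/route/regime/statistic doses (mg/kg day, or
#'       mg/kg for the acute regime);}
#'     \item{risks}{per chemical/route/kind/statistic risk values with
#'       `acceptable` flags and reference provenance;}
#'     \item{totals}{route-level hazard index, total cancer and acute risk
#'       with cross-route percentage shares, per statistic.}
#'   }
#' @seealso [summary.risk_assessment()], [simulate.risk_assessment()],
#'   [risk_totals()]
#' @export
#' @examples
#' fit <- risk_assessment()
#' summary(fit)
risk_assessment <- function(summaries = packaged_summaries(),
                            refs = load_toxicity_refs(),
                            scenario = exposure_scenario(),
                            dermal_mode = c("paper_replication", "as_stated")) {
  dermal_mode <- match.arg(dermal_mode)
  stats_used <- c("min", "mean", "max")
  doses <- list()
  risks <- list()
  add_dose <- function(chemical, route, regime, statistic, value) {
    doses[[length(doses) + 1L]] <<- data.frame(
      chemical = chemical, route = route, regime = regime,
      statistic = statistic, value = value, stringsAsFactors = FALSE)
  }
  add_risk <- function(chemical, route, kind, statistic, dose, value, ref) {
    risks[[length(risks) + 1L]] <<- data.frame(
      chemical = chemical, route = route, kind = kind, statistic = statistic,
      dose = dose, value = value,
      acceptable = if (is.na(value)) NA else value <= risk_threshold(kind),
      reference_used = ref, stringsAsFactors = FALSE)
  }

  for (chem in intersect(chemical_ids(), unique(summaries$chemical))) {
    tox <- refs[refs$chemical == chem, , drop = FALSE]
    if (nrow(tox) != 1L) {
      stop("no toxicity reference row for ", chem, call. = FALSE)
    }
    aer <- summaries[summaries$chemical == chem &
                       summaries$matrix == "aerosol", , drop = FALSE]
    liq <- summaries[summaries$chemical == chem &
                       summaries$matrix == "e-liquid", , drop = FALSE]
    for (st in stats_used) {
      if (nrow(aer) == 1L) {
        d_inh <- dose_inhalation(aer[[st]], scenario)
        add_dose(chem, "inhalation", "chronic", st, d_inh)
        ref <- noncancer_reference_dose(chem, "inhalation", refs, scenario)
        add_risk(chem, "inhalation", "noncancer", st, d_inh,
                 if (is.na(ref$value)) NA_real_
                 else hazard_quotient(d_inh, ref$value), ref$provenance)
        add_risk(chem, "inhalation", "cancer", st, d_inh,
                 if (is.na(tox$cpv_inh)) NA_real_
                 else cancer_risk(d_inh, tox$cpv_inh),
                 if (is.na(tox$cpv_inh)) "none" else "CPV_inh")
      }
      if (nrow(liq) == 1L) {
        d_oral <- dose_oral(liq[[st]], scenario)
        d_derm <- dose_dermal(liq[[st]], chem, scenario, dermal_mode)
        i_acute <- acute_intake(liq[[st]], scenario)
        add_dose(chem, "oral", "chronic", st, d_oral)
        add_dose(chem, "dermal", "chronic", st, d_derm)
        add_dose(chem, "oral", "acute", st, i_acute)
        add_dose(chem, "dermal", "acute", st, i_acute)
        ref_o <- noncancer_reference_dose(chem, "oral", refs, scenario)
        add_risk(chem, "oral", "noncancer", st, d_oral,
                 if (is.na(ref_o$value)) NA_real_
                 else hazard_quotient(d_oral, ref_o$value), ref_o$provenance)
        ref_d <- noncancer_reference_dose(chem, "dermal", refs, scenario)
        add_risk(chem, "dermal", "noncancer", st, d_derm,
                 if (is.na(ref_d$value)) NA_real_
                 else hazard_quotient(d_derm, ref_d$value), ref_d$provenance)
        add_risk(chem, "oral", "cancer", st, d_oral,
                 if (is.na(tox$cpv_oral)) NA_real_
                 else cancer_risk(d_oral, tox$cpv_oral),
                 if (is.na(tox$cpv_oral)) "none" else "CPV_oral")
        add_risk(chem, "dermal", "cancer", st, d_derm,
                 if (is.na(tox$sf_derm)) NA_real_
                 else cancer_risk(d_derm, tox$sf_derm),
                 if (is.na(tox$sf_derm)) "none" else "SF_derm")
        add_risk(chem, "oral", "acute", st, i_acute,
                 if (is.na(tox$ld50_oral)) NA_real_
                 else acute_risk(i_acute, tox$ld50_oral),
                 if (is.na(tox$ld50_oral)) "none" else "LD50_oral")
        add_risk(chem, "dermal", "acute", st, i_acute,
                 if (is.na(tox$ld50_derm)) NA_real_
                 else acute_risk(i_acute, tox$ld50_derm),
                 if (is.na(tox$ld50_derm)) "none" else "LD50_derm")
      }
    }
  }
  empty_doses <- data.frame(chemical = character(), route = character(),
                            regime = character(), statistic = character(),
                            value = numeric(), stringsAsFactors = FALSE)
  empty_risks <- data.frame(chemical = character(), route = character(),
                            kind = character(), statistic = character(),
                            dose = numeric(), value = numeric(),
                            acceptable = logical(),
                            reference_used = character(),
                            stringsAsFactors = FALSE)
  doses <- if (length(doses)) do.call(rbind, doses) else empty_doses
  risks <- if (length(risks)) do.call(rbind, risks) else empty_risks
  obj <- structure(list(doses = doses, risks = risks,
                        summaries = summaries, refs = refs,
                        scenario = scenario, dermal_mode = dermal_mode),
                   class = "risk_assessment")
  obj$totals <- do.call(rbind, lapply(stats_used, function(st) {
    risk_totals(obj, statistic = st)
  }))
  obj
}

#' Route-level risk totals and cross-route shares
#'
#' Sums the assessed per-chemical risks into route totals: the hazard index
#' (sum of hazard quotients), the total cancer risk and the total acute risk,
#' with no interaction terms. Shares are each route's percentage of the sum
#' over routes within one kind. Chemicals without a reference value cannot
#' contribute and are excluded; a route/kind group with no assessed chemical
#' reports a zero total with `n_assessed = 0`.
#'
#' @param x A [risk_assessment()].
#' @param statistic `"mean"` for average-concentration totals, `"max"` for
#'   the worst case combining all per-chemical maxima simultaneously (a
#'   deliberately pessimistic, physically co-occurring upper bound), or
#'   `"min"`.
#' @return A data frame with columns `statistic`, `kind`, `route`, `total`,
#'   `n_assessed`, `share_pct`.
#' @export
risk_totals <- function(x, statistic = "mean") {
  stopifnot(inherits(x, "risk_assessment"))
  r <- x$risks[x$risks$statistic == statistic, , drop = FALSE]
  if (nrow(r) == 0L) {
    return(data.frame(statistic = character(), kind = character(),
                      route = character(), total = numeric(),
                      n_assessed = integer(), share_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  combos <- unique(r[c("kind", "route")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    g <- r[r$kind == combos$kind[i] & r$route == combos$route[i], ,
           drop = FALSE]
    assessed <- g$value[!is.na(g$value)]
    data.frame(statistic = statistic, kind = combos$kind[i],
               route = combos$route[i],
               total = sum(assessed), n_assessed = length(assessed),
               stringsAsFactors = FALSE)
  }))
  out$share_pct <- NA_real_
  for (k in unique(out$kind)) {
    idx <- out$kind == k
    denom <- sum(out$total[idx])
    out$share_pct[idx] <- if (denom > 0) out$total[idx] / denom * 100 else NA
  }
  rownames(out) <- NULL
  out
}

#' @export
print.risk_assessment <- function(x, ...) {
  n_chem <- length(unique(x$risks$chemical))
  cat("Multi-route health risk assessment\n")
  cat(sprintf("  %d chemicals, dermal mode '%s'\n", n_chem, x$dermal_mode))
  tot <- x$totals[x$totals$statistic == "mean", , drop = FALSE]
  hi <- tot[tot$kind == "noncancer" & tot$route == "inhalation", "total"]
  cr <- tot[tot$kind == "cancer" & tot$route == "inhalation", "total"]
  if (length(hi)) cat(sprintf("  mean inhalation hazard index: %.2f\n", hi))
  if (length(cr)) {
    cat(sprintf("  mean inhalation total cancer risk: %.3g\n", cr))
  }
  cat("Use summary() for the full per-chemical tables.\n")
  invisible(x)
}

#' Summarize a risk assessment as per-route tables
#'
#' @param object A [risk_assessment()].
#' @param ... Unused.
#' @return A list of class `summary.risk_assessment` with wide per-chemical
#'   tables (`doses`, `cancer`, `hq`, `acute`), the `totals` data frame and
#'   metadata; its print method displays values in scientific notation with
#'   3 significant digits.
#' @export
summary.risk_assessment <- function(object, ...) {
  wide <- function(kind) {
    r <- object$risks[object$risks$kind == kind, , drop = FALSE]
    if (nrow(r) == 0L) {
      return(data.frame(chemical = character(), route = character(),
                        min = numeric(), mean = numeric(), max = numeric(),
                        stringsAsFactors = FALSE))
    }
    out <- stats::reshape(
      r[c("chemical", "route", "statistic", "value")],
      idvar = c("chemical", "route"), timevar = "statistic",
      direction = "wide")
    names(out) <- sub("^value\\.", "", names(out))
    rownames(out) <- NULL
    out[order(match(out$chemical, chemical_ids()), out$route), ]
  }
  dose_wide <- if (nrow(object$doses) == 0L) {
    data.frame(chemical = character(), route = character(),
               regime = character(), min = numeric(), mean = numeric(),
               max = numeric(), stringsAsFactors = FALSE)
  } else {
    dw <- stats::reshape(
      object$doses[c("chemical", "route", "regime", "statistic", "value")],
      idvar = c("chemical", "route", "regime"), timevar = "statistic",
      direction = "wide")
    names(dw) <- sub("^value\\.", "", names(dw))
    rownames(dw) <- NULL
    dw
  }
  structure(list(doses = dose_wide, cancer = wide("cancer"),
                 hq = wide("noncancer"), acute = wide("acute"),
                 totals = object$totals, dermal_mode = object$dermal_mode),
            class = "summary.risk_assessment")
}

fmt3 <- function(x) {
  ifelse(is.na(x), "-", formatC(x, format = "e", digits = 2))
}

#' @export
print.summary.risk_assessment <- function(x, ...) {
  show <- function(d, title) {
    cat("\n", title, "\n", sep = "")
    disp <- d
    for (col in intersect(c("min", "mean", "max"), names(disp))) {
      disp[[col]] <- fmt3(disp[[col]])
    }
    print(disp, row.names = FALSE)
  }
  cat(sprintf("Risk assessment (dermal mode '%s')\n", x$dermal_mode))
  show(x$doses, "Doses (mg/kg day chronic; mg/kg acute):")
  show(x$cancer, "Cancer risk (acceptable <= 1e-6):")
  show(x$hq, "Hazard quotients (acceptable <= 1):")
  show(x$acute, "Acute risk ratios (acceptable <= 1):")
  cat("\nRoute totals:\n")
  tot <- x$totals
  tot$total <- fmt3(tot$total)
  tot$share_pct <- ifelse(is.na(tot$share_pct), "-",
                          sprintf("%.2f", tot$share_pct))
  print(tot, row.names = FALSE)
  invisible(x)
}

#' Plot per-chemical risks
#'
#' Horizontal bar charts of the mean hazard quotients and cancer risks by
#' chemical for one route, on a log axis, with the acceptability threshold
#' marked.
#'
#' @param x A [risk_assessment()].
#' @param route Exposure route to display.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.risk_assessment <- function(x, route = "inhalation", ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 6, 2, 1))
  on.exit(graphics::par(old))
  for (kind in c("noncancer", "cancer")) {
    r <- x$risks[x$risks$kind == kind & x$risks$route == route &
                   x$risks$statistic == "mean", , drop = FALSE]
    r <- r[!is.na(r$value) & r$value > 0, , drop = FALSE]
    if (nrow(r) == 0L) next
    graphics::barplot(r$value, names.arg = r$chemical, horiz = TRUE,
                      las = 1, log = "x",
                      main = if (kind == "noncancer") "Hazard quotient"
                             else "Cancer risk",
                      xlab = route, ...)
    graphics::abline(v = risk_threshold(kind), lty = 2)
  }
  invisible(x)
}
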