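#' The study chemical registry
#'
#' The assessment covers eleven chemicals measured in e-cigarette aerosols and
#' e-liquids: four organic compounds produced mainly by heating the e-liquid
#' solvents (formaldehyde, acetaldehyde, acetone, acrolein) and seven heavy
#' metals that migrate from device components (As, Cd, Mn, Pb, Cu, Ni, Cr).
#' Chromium is treated as hexavalent throughout, the more hazardous oxidation
#' state, because source studies rarely speciate it.
#'
#' @return A data frame with one row per chemical and columns `id`,
#'   `display_name`, `is_metal` and `notes`.
#' @export
#' @examples
#' era_chemicals()
era_chemicals <- function() {
  data.frame(
    id = c("formaldehyde", "acetaldehyde", "acetone", "acrolein",
           "As", "Cd", "Mn", "Pb", "Cu", "Ni", "Cr"),
    display_name = c("Formaldehyde", "Acetaldehyde", "Acetone", "Acrolein",
                     "Arsenic", "Cadmium", "Manganese", "Lead",
                     "Copper", "Nickel", "Chromium"),
    is_metal = c(FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    notes = c("IARC group 1", "IARC group 2B", "", "IARC group 2A",
              "", "IARC group 1 (2017)", "", "IARC group 2B (2017)",
              "", "", "treated as hexavalent"),
    stringsAsFactors = FALSE
  )
}

chemical_ids <- function() era_chemicals()$id

#' @keywords internal
assert_chemical <- function(chemical) {
  bad <- setdiff(chemical, chemical_ids())
  if (length(bad)) {
    stop("unknown chemical id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(chemical)
}

TOX_COLS <- c("chemical", "rel_ug_m3", "rfc_ug_m3", "cpv_inh", "rfd_oral",
              "cpv_oral", "rfd_derm", "sf_derm", "ld50_oral", "ld50_derm",
              "source")

#' Load toxicity reference values
#'
#' Reads one or more CSV files of regulatory reference values and merges them
#' into a single table with one row per chemical. Each file uses the header
#' `chemical,rel_ug_m3,rfc_ug_m3,cpv_inh,rfd_oral,cpv_oral,rfd_derm,sf_derm,
#' ld50_oral,ld50_derm,source`; an empty field is a missing value ("no
#' reference found"), never zero. With `path = NULL` the packaged tables are
#' loaded: OEHHA reference exposure levels (REL, ug/m3) and cancer potency
#' values (CPV, (mg/kg day)^-1), USEPA reference concentrations (RfC, ug/m3)
#' and reference doses (RfD, mg/kg day), dermal/oral slope factors, and
#' route-specific LD50s (mg/kg).
#'
#' @param path `NULL` for the packaged tables, otherwise a character vector of
#'   CSV paths in the documented dialect.
#' @return A data frame of class `toxicity_refs`, one row per chemical.
#' @export
#' @examples
#' refs <- load_toxicity_refs()
#' subset(refs, chemical == "Cr")
load_toxicity_refs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tables",
                        c("toxicity_inhalation.csv", "toxicity_dermal.csv",
                          "toxicity_oral.csv"),
                        package = "vaporisk", mustWork = TRUE)
  }
  pieces <- lapply(path, read_toxicity_csv)
  raw <- do.call(rbind, pieces)
  if (nrow(raw) == 0L) {
    warning("empty toxicity reference input; returning empty table")
    out <- raw
    class(out) <- c("toxicity_refs", class(out))
    return(out)
  }
  # coalesce across files: a value may only be defined in one of them
  merged <- lapply(split(raw, raw$chemical), function(d) {
    out <- d[1L, , drop = FALSE]
    for (col in setdiff(TOX_COLS, c("chemical", "source"))) {
      vals <- d[[col]][!is.na(d[[col]])]
      if (length(unique(vals)) > 1L) {
        stop("conflicting values for ", col, " of ", d$chemical[1L],
             call. = FALSE)
      }
      out[[col]] <- if (length(vals)) vals[1L] else NA_real_
    }
    out$source <- paste(unique(d$source[nzchar(d$source) & !is.na(d$source)]),
                        collapse = ";")
    out
  })
  out <- do.call(rbind, merged)
  out <- out[order(match(out$chemical, chemical_ids())), , drop = FALSE]
  rownames(out) <- NULL
  no_value <- apply(out[setdiff(TOX_COLS, c("chemical", "source"))], 1L,
                    function(r) all(is.na(r)))
  if (any(no_value)) {
    stop("chemical(s) with no reference value at all: ",
         paste(out$chemical[no_value], collapse = ", "), call. = FALSE)
  }
  class(out) <- c("toxicity_refs", class(out))
  out
}

read_toxicity_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing_cols <- setdiff(TOX_COLS, names(d))
  if (length(missing_cols)) {
    stop("toxicity CSV ", file, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- d[TOX_COLS]
  if (nrow(d) == 0L) return(d_numeric(d))
  bad <- setdiff(d$chemical, chemical_ids())
  if (length(bad)) {
    rows <- which(d$chemical %in% bad)
    stop("unknown chemical id in ", basename(file), " row(s) ",
         paste(rows, collapse = ", "), ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d <- d_numeric(d)
  num <- setdiff(TOX_COLS, c("chemical", "source"))
  for (col in num) {
    neg <- which(d[[col]] <= 0)
    if (length(neg)) {
      stop("non-positive ", col, " for ", paste(d$chemical[neg], collapse = ", "),
           " in ", basename(file), call. = FALSE)
    }
  }
  d
}

d_numeric <- function(d) {
  for (col in setdiff(TOX_COLS, c("chemical", "source"))) {
    v <- d[[col]]
    v[!nzchar(trimws(v))] <- NA_character_
    d[[col]] <- as.numeric(v)
  }
  d
}

#' Write a toxicity reference table to CSV
#'
#' Inverse of [load_toxicity_refs()]: missing values become empty fields, so a
#' written table reloads to identical records.
#'
#' @param refs A `toxicity_refs` data frame.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_toxicity_refs <- function(refs, file) {
  out <- as.data.frame(refs)[TOX_COLS]
  utils::write.csv(out, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Select the non-cancer reference dose for a chemical and route
#'
#' Chronic non-cancer risk compares a daily dose with a reference level. For
#' the inhalation route two concentration thresholds may exist for the same
#' chemical (the OEHHA REL and the USEPA RfC, both ug/m3); each is converted
#' to a dose via `c * breathing_volume / BW / 1000` (mg/kg day) and the
#' *smaller* converted value is used, the conservative choice. For the oral
#' and dermal routes the applicable RfD (mg/kg day) is returned directly.
#'
#' @param chemical A chemical id from [era_chemicals()].
#' @param route One of `"inhalation"`, `"oral"`, `"dermal"`.
#' @param refs A `toxicity_refs` table from [load_toxicity_refs()].
#' @param scenario An [exposure_scenario()] (supplies breathing volume and
#'   body weight for the inhalation conversion).
#' @return A list of class `reference_dose` with elements `chemical`, `route`,
#'   `value` (mg/kg day) and `provenance` (`"REL"`, `"RfC"`, `"RfD_oral"` or
#'   `"RfD_derm"`). When no threshold exists for the route, `value` is `NA`
#'   and `provenance` is `"none"`: the assessment is *not performed*, which is
#'   distinct from a zero risk.
#' @export
#' @examples
#' refs <- load_toxicity_refs()
#' noncancer_reference_dose("acrolein", "inhalation", refs, exposure_scenario())
noncancer_reference_dose <- function(chemical, route, refs,
                                     scenario = exposure_scenario()) {
  assert_chemical(chemical)
  route <- match.arg(route, c("inhalation", "oral", "dermal"))
  row <- refs[refs$chemical == chemical, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("chemical ", chemical, " not present in reference table",
         call. = FALSE)
  }
  if (route == "inhalation") {
    conc <- c(REL = row$rel_ug_m3, RfC = row$rfc_ug_m3)
    conc <- conc[!is.na(conc)]
    if (length(conc)) {
      dose <- conc * scenario$breathing_volume / scenario$bw / 1000
      i <- which.min(dose)
      return(new_reference_dose(chemical, route, unname(dose[i]),
                                names(conc)[i]))
    }
  } else if (route == "oral") {
    if (!is.na(row$rfd_oral)) {
      return(new_reference_dose(chemical, route, row$rfd_oral, "RfD_oral"))
    }
  } else {
    if (!is.na(row$rfd_derm)) {
      return(new_reference_dose(chemical, route, row$rfd_derm, "RfD_derm"))
    }
  }
  new_reference_dose(chemical, route, NA_real_, "none")
}

new_reference_dose <- function(chemical, route, value, provenance) {
  structure(list(chemical = chemical, route = route, value = value,
                 provenance = provenance),
            class = "reference_dose")
}

#' @export
print.reference_dose <- function(x, ...) {
  if (is.na(x$value)) {
    cat(sprintf("<reference_dose> %s / %s: no reference available\n",
                x$chemical, x$route))
  } else {
    cat(sprintf("<reference_dose> %s / %s: %.4g mg/kg day (from %s)\n",
                x$chemical, x$route, x$value, x$provenance))
  }
  invisible(x)
}
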