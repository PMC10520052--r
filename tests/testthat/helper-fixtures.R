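# shared fixtures built in code

default_scenario <- exposure_scenario()
packaged_refs <- load_toxicity_refs()
packaged_conc <- packaged_summaries()

# a minimal sample-level table in the CSV dialect
sample_records <- function() {
  rbind(
    data.frame(chemical = "formaldehyde", matrix = "aerosol",
               value = c(0, 28.1), unit = "ug/puff",
               study_id = "a1", report_kind = "range_only"),
    data.frame(chemical = "formaldehyde", matrix = "aerosol",
               value = c(0.2, 0.4, 0.6), unit = "ug/puff",
               study_id = "a2", report_kind = "per_power_series"),
    data.frame(chemical = "formaldehyde", matrix = "aerosol",
               value = 150, unit = "ng/puff",
               study_id = "a3", report_kind = "individual"),
    data.frame(chemical = "Cd", matrix = "e-liquid",
               value = 75.8, unit = "ug/ml",
               study_id = "b1", report_kind = "mean_only")
  )
}

# construct a conc_fit directly (documented structure), e.g. a point mass
make_fit <- function(key, family, params, zero_w = 0, n = 10) {
  structure(list(variable = key, family = family, params = params,
                 zero_w = zero_w, gof = NULL, n = n, values = NULL),
            class = "conc_fit")
}

point_mass_fits <- function(summaries, at = "mean") {
  fits <- lapply(seq_len(nrow(summaries)), function(i) {
    key <- paste(summaries$chemical[i], summaries$matrix[i], sep = "|")
    make_fit(key, "point_mass", list(value = summaries[[at]][i]))
  })
  names(fits) <- paste(summaries$chemical, summaries$matrix, sep = "|")
  fits
}
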