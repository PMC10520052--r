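test_that("the registry holds exactly the eleven study chemicals", {
  chems <- era_chemicals()
  expect_equal(nrow(chems), 11L)
  expect_false(any(duplicated(chems$id)))
  expect_setequal(chems$id,
                  c("formaldehyde", "acetaldehyde", "acetone", "acrolein",
                    "As", "Cd", "Mn", "Pb", "Cu", "Ni", "Cr"))
  expect_equal(sum(chems$is_metal), 7L)
})

test_that("packaged toxicity tables carry the resolved reference values", {
  refs <- packaged_refs
  expect_equal(nrow(refs), 11L)
  f <- refs[refs$chemical == "formaldehyde", ]
  expect_equal(f$rel_ug_m3, 9)
  expect_equal(f$cpv_inh, 0.021)
  expect_true(is.na(f$rfc_ug_m3))
  cr <- refs[refs$chemical == "Cr", ]
  expect_equal(cr$rel_ug_m3, 0.2)
  expect_equal(cr$cpv_inh, 510)
  expect_equal(cr$rfc_ug_m3, 0.0083)
  num <- refs[setdiff(names(refs), c("chemical", "source"))]
  expect_true(all(num > 0, na.rm = TRUE))
  # every chemical has at least one usable reference value
  expect_false(any(apply(num, 1L, function(r) all(is.na(r)))))
})

test_that("toxicity tables round-trip through CSV bit-exactly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_toxicity_refs(packaged_refs, tmp)
  back <- load_toxicity_refs(tmp)
  expect_identical(as.data.frame(back), as.data.frame(packaged_refs))
})

test_that("malformed toxicity inputs are rejected and empty input warns", {
  hdr <- paste(c("chemical", "rel_ug_m3", "rfc_ug_m3", "cpv_inh", "rfd_oral",
                 "cpv_oral", "rfd_derm", "sf_derm", "ld50_oral", "ld50_derm",
                 "source"), collapse = ",")
  bad_chem <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, "plutonium,1,,,,,,,,,x"), bad_chem)
  expect_error(load_toxicity_refs(bad_chem), "unknown chemical.*plutonium")
  bad_val <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, "Cr,-0.2,,,,,,,,,x"), bad_val)
  expect_error(load_toxicity_refs(bad_val), "non-positive")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(hdr, empty)
  expect_warning(out <- load_toxicity_refs(empty), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("inhalation reference dose applies the minimum-reference rule", {
  rd <- noncancer_reference_dose("acrolein", "inhalation", packaged_refs,
                                 default_scenario)
  expect_equal(rd$value, 0.02 * 20 / 70 / 1000, tolerance = 1e-12)
  expect_equal(rd$provenance, "RfC")
  # single-candidate case
  rd_f <- noncancer_reference_dose("formaldehyde", "inhalation",
                                   packaged_refs, default_scenario)
  expect_equal(rd_f$value, 9 * 20 / 70 / 1000, tolerance = 1e-12)
  expect_equal(rd_f$provenance, "REL")
  # the returned dose never exceeds any converted candidate
  for (chem in c("acrolein", "Mn", "Cr", "acetaldehyde")) {
    row <- packaged_refs[packaged_refs$chemical == chem, ]
    cand <- c(row$rel_ug_m3, row$rfc_ug_m3)
    cand <- cand[!is.na(cand)] * 20 / 70 / 1000
    rd_c <- noncancer_reference_dose(chem, "inhalation", packaged_refs,
                                     default_scenario)
    expect_true(all(rd_c$value <= cand + 1e-15))
  }
})

test_that("inhalation reference conversion is linear in body weight", {
  s1 <- exposure_scenario(bw = 70)
  s2 <- exposure_scenario(bw = 140)
  r1 <- noncancer_reference_dose("acrolein", "inhalation", packaged_refs, s1)
  r2 <- noncancer_reference_dose("acrolein", "inhalation", packaged_refs, s2)
  expect_equal(r2$value, r1$value / 2, tolerance = 1e-12)
})

test_that("a chemical without a route threshold signals 'no reference'", {
  rd <- noncancer_reference_dose("acetone", "inhalation", packaged_refs,
                                 default_scenario)
  expect_true(is.na(rd$value))
  expect_equal(rd$provenance, "none")
  # oral and dermal return the plain RfD
  rd_o <- noncancer_reference_dose("Cd", "oral", packaged_refs,
                                   default_scenario)
  expect_equal(rd_o$value, 0.0005)
  rd_d <- noncancer_reference_dose("Cd", "dermal", packaged_refs,
                                   default_scenario)
  expect_equal(rd_d$value, 0.00001)
})
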