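test_that("FHIR wrapper carries the plstring.org system at version 1.0", {
  plsc <- pl_decode("who#3.58.0#HLA-A*02:01")
  json <- pl_to_fhir(plsc)
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  coding <- doc$valueCodeableConcept$coding[[1]]
  expect_equal(coding$system, "plstring.org")
  expect_equal(coding$version, "1.0")
  expect_equal(coding$code, "who#3.58.0#HLA-A*02:01")

  back <- pl_from_fhir(json)
  expect_equal(pl_plsc_text(back$plsc), pl_plsc_text(plsc))
})

test_that("FHIR extraction tolerates the variant spelling and foreign systems", {
  variant <- '{"valueCodableConcept":{"coding":[{"system":"plstring.org","version":"1.0","code":"who#3.58.0#B*07:02"}]}}'
  expect_warning(out <- pl_from_fhir(variant), "valueCodableConcept")
  expect_equal(out$plsc$plstring_text, "B*07:02")

  loinc <- '{"valueCodeableConcept":{"coding":[{"system":"loinc.org","code":"12345-6"}]}}'
  expect_pl_error(pl_from_fhir(loinc), "NO_PLSTRING_CODING")

  # the first plstring.org coding wins among several
  mixed <- '{"valueCodeableConcept":{"coding":[{"system":"loinc.org","code":"1"},{"system":"plstring.org","version":"1.0","code":"optn#2025-01-15#A2"}]}}'
  expect_equal(pl_from_fhir(mixed)$plsc$namespace_id, "optn")
})

test_that("HAML bead observations round-trip", {
  bead <- pl_bead_observation("who#3.58.0#HLA-A*02:01", 10543, "positive")
  xml <- pl_to_haml(bead)
  doc <- xml2::read_xml(xml)
  expect_equal(xml2::xml_name(doc), "target-bead-observation")
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "./HLA-target-type")),
               "who#3.58.0#HLA-A*02:01")
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "./bead-interpretation")),
               "positive")
  back <- pl_from_haml(xml)
  expect_s3_class(back, "pl_bead_observation")
  expect_equal(back$raw_value, 10543)
  expect_equal(pl_plsc_text(back$target_type), "who#3.58.0#HLA-A*02:01")

  expect_pl_error(pl_bead_observation("who#3.58.0#A*02:01", 1, "equivocal"),
                  "BAD_QUALIFIER")
})

test_that("HAML assay interpretations carry positive and negative PLSCs", {
  ai <- pl_assay_interpretation("who#3.58.0#A*01:01+B*07:02",
                                "who#3.58.0#A*02:01",
                                comment = "current and historic sera")
  xml <- pl_to_haml(ai)
  doc <- xml2::read_xml(xml)
  strings <- xml2::xml_text(
    xml2::xml_find_all(doc, "./specificities/specificities-string"))
  expect_length(strings, 2L)
  back <- pl_from_haml(xml)
  expect_equal(pl_plsc_text(back$positive), "who#3.58.0#A*01:01+B*07:02")
  expect_equal(pl_plsc_text(back$negative), "who#3.58.0#A*02:01")
  expect_equal(back$comment, "current and historic sera")

  # namespace/version must agree across the two PLSCs of one record
  expect_pl_error(
    pl_assay_interpretation("who#3.58.0#A*01:01", "optn#2025-01-15#A2"),
    "NAMESPACE_MIXING"
  )
})

test_that("HAML diagnostic reports type their specificities", {
  rep <- pl_diagnostic_report("optn#2025-01-15#A2+B57", type = "Unacceptable")
  xml <- pl_to_haml(rep)
  doc <- xml2::read_xml(xml)
  expect_equal(
    xml2::xml_text(xml2::xml_find_first(doc, "./specificities/specificities-type")),
    "Unacceptable")
  back <- pl_from_haml(xml)
  expect_equal(back$type, "Unacceptable")
  expect_equal(pl_plsc_text(back$specificities), "optn#2025-01-15#A2+B57")

  expect_pl_error(pl_diagnostic_report("who#3.58.0#A*02:01", type = "Forbidden"),
                  "BAD_QUALIFIER")
})

test_that("emitted HAML uses only the modelled element names", {
  records <- list(
    pl_bead_observation("who#3.58.0#HLA-A*02:01", 123, "negative"),
    pl_assay_interpretation("who#3.58.0#A*01:01", "who#3.58.0#A*02:01", "c"),
    pl_diagnostic_report("who#3.58.0#B*07:02", "Acceptable", "ctx")
  )
  allowed <- c("target-bead-observation", "HLA-target-type", "bead-raw-data",
               "bead-interpretation", "assay-interpretation", "specificities",
               "specificities-string", "interpretation-context",
               "interpretation-context-comment", "diagnostic-report",
               "specificities-type")
  for (r in records) {
    doc <- xml2::read_xml(pl_to_haml(r))
    names <- unique(c(xml2::xml_name(doc),
                      xml2::xml_name(xml2::xml_find_all(doc, ".//*"))))
    expect_true(all(names %in% allowed))
  }
  expect_pl_error(pl_from_haml("<bead-panel><x/></bead-panel>"),
                  "UNKNOWN_HAML_ELEMENT")
  expect_pl_error(pl_from_haml("<target-bead-observation></target-bead-observation>"),
                  "MISSING_ELEMENT")
})

test_that("carrier conversion preserves the PLSC payload byte-for-byte", {
  plsc <- pl_decode("who#3.58.0#HLA-DQA1*05:01~HLA-DQB1*02:01")
  fhir <- pl_to_fhir(plsc)
  conv1 <- pl_convert(fhir, from = "fhir", to = "haml")
  conv2 <- pl_convert(conv1$output, from = "haml", to = "fhir")
  code1 <- jsonlite::fromJSON(fhir, simplifyVector = FALSE)$valueCodeableConcept$coding[[1]]$code
  code2 <- jsonlite::fromJSON(conv2$output, simplifyVector = FALSE)$valueCodeableConcept$coding[[1]]$code
  expect_identical(code1, code2)

  # lossy carrier fields are reported, not dropped silently
  bead <- pl_bead_observation("who#3.58.0#A*02:01", 9876, "positive")
  conv <- pl_convert(pl_to_haml(bead), from = "haml", to = "fhir")
  expect_true("bead-raw-data" %in% conv$unmapped)

  expect_error(pl_convert("<not-xml", from = "haml", to = "fhir"))
})
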