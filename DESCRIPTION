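Package: plstring
Title: Parse, Validate and Exchange HLA Phenotype List Strings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the phenotype list (PL) String grammar used to report
    antigen- and protein-level HLA data from antibody assays and their clinical
    interpretation. Provides a tokenizer and operator-precedence parser for the
    four PL String delimiters ('+', '/', '~', '%'), detection of genotype list
    (GL) String-only delimiters, validation of atoms against governed namespace
    vocabularies (WHO, OPTN, ET, NMDP) including heterodimer alpha/beta pairing
    rules and multiple allele code (MAC) expansion, exact possible-phenotype
    ("worlds") semantics with must/may presence queries, encoding and decoding
    of PL String Codes (PLSCs), and embedding of PLSCs in HL7 FHIR-style
    CodeableConcept JSON and HAML-style XML report fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
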