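# Carrier formats: FHIR-style valueCodeableConcept JSON and HAML-style XML
# report fragments. Only a minimal, documented profile of each carrier is
# modelled: the CodeableConcept coding fragment on the FHIR side, and the
# bead-observation, assay-interpretation and diagnostic-report fragment
# shapes on the HAML side.

FHIR_SYSTEM <- "plstring.org"
FHIR_VERSION <- "1.0"
SPECIFICITY_TYPES <- c("Present", "Acceptable", "Unacceptable")

HAML_ELEMENTS <- c(
  "target-bead-observation", "HLA-target-type", "bead-raw-data",
  "bead-interpretation", "assay-interpretation", "specificities",
  "specificities-string", "interpretation-context",
  "interpretation-context-comment", "diagnostic-report", "specificities-type"
)

as_plsc <- function(x, vocab = NULL) {
  if (inherits(x, "pl_plsc")) x else pl_decode(x, vocab)
}

#' Wrap a PLSC in a FHIR-style valueCodeableConcept JSON fragment
#'
#' Emits the compact JSON fragment used to carry a PLSC in an HL7 FHIR
#' Observation: the PLSC is the `code` of a `coding` under the
#' `plstring.org` code system, code-system version `1.0`.
#'
#' @param plsc A `pl_plsc` or PLSC text.
#' @param system_version The code-system version (default `"1.0"`).
#' @param display Optional human-readable display string.
#' @return A single JSON string.
#' @export
#' @examples
#' pl_to_fhir(pl_decode("who#3.58.0#HLA-A*02:01"))
pl_to_fhir <- function(plsc, system_version = FHIR_VERSION, display = NULL) {
  plsc <- as_plsc(plsc)
  coding <- list(system = FHIR_SYSTEM, version = system_version,
                 code = pl_plsc_text(plsc))
  if (!is.null(display)) coding$display <- display
  as.character(jsonlite::toJSON(
    list(valueCodeableConcept = list(coding = list(coding))),
    auto_unbox = TRUE
  ))
}

#' Extract a PLSC from a FHIR-style valueCodeableConcept fragment
#'
#' Accepts both the standard `valueCodeableConcept` spelling and the
#' `valueCodableConcept` variant seen in the wild (the latter with a
#' warning), finds the first coding under the `plstring.org` system, and
#' decodes its code.
#'
#' @param json_text JSON text of the fragment.
#' @param vocab Optional `pl_vocabulary` for payload validation.
#' @return A list with `plsc` (a `pl_plsc`) and `coding` (a list with
#'   `system`, `version`, `code`, and `display` if present).
#' @export
pl_from_fhir <- function(json_text, vocab = NULL) {
  doc <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  cc <- doc[["valueCodeableConcept"]]
  if (is.null(cc)) {
    cc <- doc[["valueCodableConcept"]]
    if (!is.null(cc)) {
      warning("input uses the 'valueCodableConcept' spelling; accepting it",
              call. = FALSE)
    }
  }
  if (is.null(cc) || is.null(cc$coding)) {
    pl_abort("NO_PLSTRING_CODING",
             "no valueCodeableConcept.coding element found")
  }
  codings <- cc$coding
  hit <- NULL
  for (c in codings) {
    if (identical(c$system, FHIR_SYSTEM)) { hit <- c; break }
  }
  if (is.null(hit)) {
    pl_abort("NO_PLSTRING_CODING",
             sprintf("no coding with system '%s' present", FHIR_SYSTEM))
  }
  list(plsc = pl_decode(hit$code, vocab), coding = hit)
}

#' HAML-style report records
#'
#' Constructors for the three HAML fragment shapes that carry PLSCs:
#' `pl_bead_observation()` describes one single-antigen bead (its target
#' composition, raw assay signal and per-bead interpretation);
#' `pl_assay_interpretation()` carries the positive and negative antibody
#' specificities concluded from an assay; `pl_diagnostic_report()` carries a
#' clinically interpreted specificity list typed as Present, Acceptable or
#' Unacceptable.
#'
#' @param target_type,positive,negative,specificities A `pl_plsc` or PLSC
#'   text.
#' @param raw_value Optional numeric assay signal for the bead.
#' @param interpretation A qualifier: `positive`, `negative` or
#'   `inconclusive`.
#' @param comment,patient_context Optional free-text context.
#' @param type One of `Present`, `Acceptable`, `Unacceptable`.
#' @return A record object of class `pl_bead_observation`,
#'   `pl_assay_interpretation` or `pl_diagnostic_report`.
#' @export
pl_bead_observation <- function(target_type, raw_value = NULL,
                                interpretation = "positive") {
  if (!interpretation %in% QUALIFIERS) {
    pl_abort("BAD_QUALIFIER",
             sprintf("bead interpretation must be one of %s",
                     paste(QUALIFIERS, collapse = ", ")))
  }
  structure(list(target_type = as_plsc(target_type),
                 raw_value = if (is.null(raw_value)) NULL else as.numeric(raw_value),
                 interpretation = interpretation),
            class = "pl_bead_observation")
}

#' @rdname pl_bead_observation
#' @export
pl_assay_interpretation <- function(positive, negative, comment = NULL) {
  pos <- as_plsc(positive); neg <- as_plsc(negative)
  if (pos$namespace_id != neg$namespace_id ||
      pos$version_token != neg$version_token) {
    pl_abort("NAMESPACE_MIXING",
             "positive and negative specificities must share one namespace and version")
  }
  structure(list(positive = pos, negative = neg, comment = comment),
            class = "pl_assay_interpretation")
}

#' @rdname pl_bead_observation
#' @export
pl_diagnostic_report <- function(specificities, type = "Unacceptable",
                                 patient_context = NULL) {
  if (!type %in% SPECIFICITY_TYPES) {
    pl_abort("BAD_QUALIFIER",
             sprintf("specificities type must be one of %s",
                     paste(SPECIFICITY_TYPES, collapse = ", ")))
  }
  structure(list(specificities = as_plsc(specificities), type = type,
                 patient_context = patient_context),
            class = "pl_diagnostic_report")
}

xml_elem <- function(parent, name, text = NULL) {
  stopifnot(name %in% HAML_ELEMENTS)
  node <- xml2::xml_add_child(parent, name)
  if (!is.null(text)) xml2::xml_set_text(node, as.character(text))
  node
}

#' Serialize a HAML-style record to XML
#'
#' Emits a well-formed XML fragment using only the element names of the
#' three modelled fragment shapes (ASCII hyphens). Embedded PLSCs are
#' always element text content, never attributes.
#'
#' @param record A `pl_bead_observation`, `pl_assay_interpretation` or
#'   `pl_diagnostic_report`.
#' @return A single XML string.
#' @export
#' @examples
#' bead <- pl_bead_observation("who#3.58.0#HLA-A*02:01", 10543, "positive")
#' cat(pl_to_haml(bead))
pl_to_haml <- function(record) {
  UseMethod("pl_to_haml")
}

haml_string <- function(doc) {
  s <- as.character(doc)
  sub("^<\\?xml[^>]*\\?>\\s*", "", s)
}

#' @export
pl_to_haml.pl_bead_observation <- function(record) {
  doc <- xml2::xml_new_root("target-bead-observation")
  xml_elem(doc, "HLA-target-type", pl_plsc_text(record$target_type))
  if (!is.null(record$raw_value)) {
    xml_elem(doc, "bead-raw-data", format(record$raw_value, scientific = FALSE,
                                          trim = TRUE))
  }
  xml_elem(doc, "bead-interpretation", record$interpretation)
  haml_string(doc)
}

#' @export
pl_to_haml.pl_assay_interpretation <- function(record) {
  doc <- xml2::xml_new_root("assay-interpretation")
  for (side in c("positive", "negative")) {
    spec <- xml_elem(doc, "specificities")
    xml_elem(spec, "specificities-type",
             if (side == "positive") "Positive" else "Negative")
    xml_elem(spec, "specificities-string", pl_plsc_text(record[[side]]))
  }
  if (!is.null(record$comment)) {
    ctx <- xml_elem(doc, "interpretation-context")
    xml_elem(ctx, "interpretation-context-comment", record$comment)
  }
  haml_string(doc)
}

#' @export
pl_to_haml.pl_diagnostic_report <- function(record) {
  doc <- xml2::xml_new_root("diagnostic-report")
  spec <- xml_elem(doc, "specificities")
  xml_elem(spec, "specificities-type", record$type)
  xml_elem(spec, "specificities-string", pl_plsc_text(record$specificities))
  if (!is.null(record$patient_context)) {
    ctx <- xml_elem(doc, "interpretation-context")
    xml_elem(ctx, "interpretation-context-comment", record$patient_context)
  }
  haml_string(doc)
}

require_child <- function(node, name) {
  child <- xml2::xml_find_first(node, paste0("./", name))
  if (inherits(child, "xml_missing")) {
    pl_abort("MISSING_ELEMENT", sprintf("required element <%s> is missing", name))
  }
  child
}

check_known_elements <- function(root) {
  names <- xml2::xml_name(xml2::xml_find_all(root, ".//*"))
  names <- c(xml2::xml_name(root), names)
  unknown <- setdiff(names, HAML_ELEMENTS)
  if (length(unknown) > 0) {
    pl_abort("UNKNOWN_HAML_ELEMENT",
             sprintf("element <%s> is not part of the modelled HAML profile",
                     unknown[1]))
  }
}

#' Parse a HAML-style XML fragment into a record
#'
#' Dispatches on the root element (`target-bead-observation`,
#' `assay-interpretation` or `diagnostic-report`) and rebuilds the
#' corresponding record, decoding every embedded PLSC.
#'
#' @param xml_text XML text of the fragment.
#' @param vocab Optional `pl_vocabulary` for payload validation.
#' @return A `pl_bead_observation`, `pl_assay_interpretation` or
#'   `pl_diagnostic_report`.
#' @export
pl_from_haml <- function(xml_text, vocab = NULL) {
  doc <- xml2::read_xml(xml_text)
  root <- xml2::xml_root(doc)
  check_known_elements(root)
  kind <- xml2::xml_name(root)
  if (kind == "target-bead-observation") {
    target <- pl_decode(xml2::xml_text(require_child(root, "HLA-target-type")), vocab)
    raw_node <- xml2::xml_find_first(root, "./bead-raw-data")
    raw <- if (inherits(raw_node, "xml_missing")) NULL else
      as.numeric(xml2::xml_text(raw_node))
    interp <- xml2::xml_text(require_child(root, "bead-interpretation"))
    return(pl_bead_observation(target, raw, interp))
  }
  if (kind == "assay-interpretation") {
    specs <- xml2::xml_find_all(root, "./specificities")
    if (length(specs) < 2L) {
      pl_abort("MISSING_ELEMENT",
               "assay-interpretation needs positive and negative <specificities>")
    }
    sides <- list()
    for (s in specs) {
      type <- tolower(xml2::xml_text(require_child(s, "specificities-type")))
      plsc <- pl_decode(xml2::xml_text(require_child(s, "specificities-string")), vocab)
      sides[[type]] <- plsc
    }
    if (is.null(sides$positive) || is.null(sides$negative)) {
      pl_abort("MISSING_ELEMENT",
               "assay-interpretation needs Positive and Negative specificities")
    }
    comment_node <- xml2::xml_find_first(
      root, "./interpretation-context/interpretation-context-comment")
    comment <- if (inherits(comment_node, "xml_missing")) NULL else
      xml2::xml_text(comment_node)
    return(pl_assay_interpretation(sides$positive, sides$negative, comment))
  }
  if (kind == "diagnostic-report") {
    spec <- require_child(root, "specificities")
    type <- xml2::xml_text(require_child(spec, "specificities-type"))
    plsc <- pl_decode(xml2::xml_text(require_child(spec, "specificities-string")), vocab)
    ctx_node <- xml2::xml_find_first(
      root, "./interpretation-context/interpretation-context-comment")
    ctx <- if (inherits(ctx_node, "xml_missing")) NULL else xml2::xml_text(ctx_node)
    return(pl_diagnostic_report(plsc, type, ctx))
  }
  pl_abort("UNKNOWN_HAML_ELEMENT",
           sprintf("unsupported root element <%s>", kind))
}

#' Convert a PLSC payload between the FHIR and HAML carriers
#'
#' The PLSC code string is carried byte-identically; carrier metadata with
#' no slot on the other side (e.g. `bead-raw-data`, which this minimal FHIR
#' profile cannot hold) is reported in `unmapped` rather than silently
#' dropped.
#'
#' @param input FHIR JSON text or HAML XML text.
#' @param from,to `"fhir"` or `"haml"`.
#' @param vocab Optional `pl_vocabulary`.
#' @return A `pl_conversion`: list with `output` (text in the target
#'   carrier), `plsc` and `unmapped` (character vector of dropped fields).
#' @export
#' @examples
#' fhir <- pl_to_fhir(pl_decode("who#3.58.0#HLA-A*02:01"))
#' conv <- pl_convert(fhir, from = "fhir", to = "haml")
#' conv$unmapped
pl_convert <- function(input, from = c("fhir", "haml"), to = c("haml", "fhir"),
                       vocab = NULL) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == to) pl_abort("BAD_QUALIFIER", "conversion requires two different carriers")
  unmapped <- character()
  if (from == "fhir") {
    parsed <- pl_from_fhir(input, vocab)
    plsc <- parsed$plsc
    if (!is.null(parsed$coding$display)) unmapped <- c(unmapped, "display")
    out <- pl_to_haml(pl_diagnostic_report(plsc, type = "Present"))
  } else {
    rec <- pl_from_haml(input, vocab)
    if (inherits(rec, "pl_bead_observation")) {
      plsc <- rec$target_type
      if (!is.null(rec$raw_value)) unmapped <- c(unmapped, "bead-raw-data")
      unmapped <- c(unmapped, "bead-interpretation")
    } else if (inherits(rec, "pl_assay_interpretation")) {
      plsc <- rec$positive
      unmapped <- c(unmapped, "negative specificities")
      if (!is.null(rec$comment)) unmapped <- c(unmapped, "interpretation-context-comment")
    } else {
      plsc <- rec$specificities
      unmapped <- c(unmapped, "specificities-type")
      if (!is.null(rec$patient_context)) {
        unmapped <- c(unmapped, "interpretation-context-comment")
      }
    }
    out <- pl_to_fhir(plsc)
  }
  structure(list(output = out, plsc = plsc, unmapped = unmapped),
            class = "pl_conversion")
}

#' @export
print.pl_conversion <- function(x, ...) {
  cat("<pl_conversion> PLSC ", pl_plsc_text(x$plsc), "\n", sep = "")
  if (length(x$unmapped) > 0) {
    cat("  unmapped:", paste(x$unmapped, collapse = ", "), "\n")
  }
  cat(x$output, "\n")
  invisible(x)
}
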