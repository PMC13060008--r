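# PL String Codes: a PL String bound to a namespace and a version-or-date,
# '#'-delimited: <namespace>#<version>#<plstring>. A PLSC carries its own
# vocabulary provenance so the reference release is identifiable without
# external metadata.

new_plsc <- function(namespace_id, version_token, plstring_text, expression) {
  structure(
    list(namespace_id = namespace_id, version_token = version_token,
         plstring_text = plstring_text, expression = expression),
    class = "pl_plsc"
  )
}

#' @export
print.pl_plsc <- function(x, ...) {
  cat("<pl_plsc> ", pl_plsc_text(x), "\n", sep = "")
  invisible(x)
}

#' Render a decoded PLSC back to its text form
#' @param plsc A `pl_plsc`.
#' @return The `namespace#version#plstring` text.
#' @export
pl_plsc_text <- function(plsc) {
  paste(plsc$namespace_id, plsc$version_token, plsc$plstring_text, sep = "#")
}

check_namespace_registered <- function(namespace_id) {
  if (!namespace_id %in% registry_table()$id) {
    pl_abort("UNKNOWN_NAMESPACE",
             sprintf("'%s' is not a registered namespace (built-ins: %s)",
                     namespace_id,
                     paste(builtin_namespaces()$id, collapse = ", ")))
  }
}

#' Encode a PL String as a PL String Code
#'
#' Binds a validated PL String to its namespace and a version token —
#' either an IPD-IMGT/HLA-style release (`3.58.0`) or, when no release
#' applies, an ISO date of reagent creation, result production or
#' interpretation. All atoms must validate against the named namespace's
#' vocabulary: mixing identifiers from different namespaces in one string is
#' not permitted.
#'
#' @param namespace_id Registered namespace token (`who`, `optn`, `et`,
#'   `nmdp`, or a registered extension).
#' @param version_token Release (`x.y.z`) or ISO date (`YYYY-MM-DD`).
#' @param plstring_text The PL String payload.
#' @param vocab A `pl_vocabulary` for the same namespace; when supplied, the
#'   payload is validated against it.
#' @param options A [pl_options()] list.
#' @return The PLSC text `namespace#version#plstring`.
#' @export
#' @examples
#' vocab <- pl_example_vocabulary("who")
#' pl_encode("who", "3.58.0", "HLA-A*02:01+HLA-B*07:02", vocab)
pl_encode <- function(namespace_id, version_token, plstring_text,
                      vocab = NULL, options = pl_options()) {
  check_namespace_registered(namespace_id)
  if (!version_token_ok(version_token)) {
    pl_abort("BAD_VERSION_TOKEN",
             sprintf("'%s' is neither a release (x.y.z) nor an ISO date (YYYY-MM-DD)",
                     version_token))
  }
  expr <- pl_parse(plstring_text, options)
  if (!is.null(vocab)) {
    if (vocab$namespace_id != namespace_id) {
      pl_abort("NAMESPACE_MIXING",
               sprintf("vocabulary is for namespace '%s', not '%s'",
                       vocab$namespace_id, namespace_id))
    }
    rep <- pl_validate(expr, vocab, options)
    if (!rep$valid) {
      first <- rep$issues[rep$issues$severity == "ERROR", ][1, ]
      pl_abort(first$code, first$message)
    }
  }
  paste(namespace_id, version_token,
        paste(attr(pl_tokenize(plstring_text, options), "normalized"), collapse = ""),
        sep = "#")
}

#' Decode a PL String Code
#'
#' Splits on the first two `#` separators, checks the namespace and version
#' token, parses the payload and, when a vocabulary is available, validates
#' every atom against it. If the first segment itself contains a PL String
#' delimiter the legacy order `plstring#namespace#version` is accepted with
#' a warning.
#'
#' @param text PLSC text.
#' @param vocab Optional `pl_vocabulary` to validate the payload against; or
#'   a resolver `function(namespace_id, version_token)` returning one.
#' @param options A [pl_options()] list.
#' @return A `pl_plsc`.
#' @export
#' @examples
#' plsc <- pl_decode("who#3.58.0#HLA-A*02:01")
#' plsc$version_token
pl_decode <- function(text, vocab = NULL, options = pl_options()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(normalize_hyphens(text))
  parts <- strsplit(text, "#", fixed = TRUE)[[1]]
  if (length(parts) != 3L || !all(nzchar(parts))) {
    pl_abort("MALFORMED_PLSC",
             "a PLSC has three '#'-separated parts: namespace#version#plstring")
  }
  if (grepl("[+/~%]", parts[1])) {
    warning("PLSC segments appear in legacy order plstring#namespace#version; reordering",
            call. = FALSE)
    parts <- parts[c(2, 3, 1)]
  }
  ns <- parts[1]; version <- parts[2]; payload <- parts[3]
  check_namespace_registered(ns)
  if (!version_token_ok(version)) {
    pl_abort("BAD_VERSION_TOKEN", sprintf("bad version token '%s'", version))
  }
  expr <- pl_parse(payload, options)
  if (is.function(vocab)) vocab <- vocab(ns, version)
  if (!is.null(vocab)) {
    if (vocab$namespace_id != ns) {
      pl_abort("NAMESPACE_MIXING",
               sprintf("vocabulary is for namespace '%s', not '%s'",
                       vocab$namespace_id, ns))
    }
    rep <- pl_validate(expr, vocab, options)
    if (!rep$valid) {
      first <- rep$issues[rep$issues$severity == "ERROR", ][1, ]
      pl_abort(first$code, first$message)
    }
  }
  new_plsc(ns, version, payload, expr)
}

#' Group dated records into one PLSC per event date
#'
#' When compositions arise from multiple dates of reagent creation, result
#' production or interpretation, a separate PLSC must be created for each
#' date. Records sharing a date are combined with `+` (multiple
#' reactivities detected).
#'
#' @param records A data frame with columns `plstring` and `event_date`
#'   (ISO `YYYY-MM-DD`).
#' @param namespace_id Registered namespace for all records.
#' @param vocab Optional `pl_vocabulary` for payload validation.
#' @return A list of `pl_plsc`, one per distinct date, ordered by date.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   plstring = c("A*02:01", "B*07:02", "A*01:01"),
#'   event_date = c("2025-01-15", "2025-01-15", "2025-02-01")
#' )
#' length(pl_split_by_event_date(recs, "who"))
pl_split_by_event_date <- function(records, namespace_id, vocab = NULL) {
  stopifnot(is.data.frame(records),
            all(c("plstring", "event_date") %in% names(records)))
  bad <- !vapply(records$event_date, version_token_ok, logical(1)) |
    !grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", records$event_date)
  if (any(bad)) {
    pl_abort("BAD_VERSION_TOKEN",
             sprintf("'%s' is not an ISO date", records$event_date[bad][1]))
  }
  dates <- sort(unique(records$event_date))
  lapply(dates, function(d) {
    texts <- records$plstring[records$event_date == d]
    combined <- paste(texts, collapse = "+")
    pl_decode(pl_encode(namespace_id, d, combined, vocab))
  })
}
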