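#' Parsing and validation options
#'
#' Bundles the switches that control how PL String text is tokenized,
#' parsed and validated.
#'
#' @param strict_percent_context Treat use of `%` between protein-level
#'   operands as an error instead of a warning-severity issue. The delimiter
#'   table restricts `%` to antigens, but published worked usage applies it to
#'   proteins and heterodimers, so the default is permissive.
#' @param tolerate_whitespace Strip whitespace found around delimiters (and at
#'   the ends of the string). Whitespace inside an atom is always an error.
#' @param normalize_unicode_hyphens Replace the Unicode hyphens U+2010, U+2011
#'   and U+2212 with ASCII `-` before tokenizing. Typeset reports routinely
#'   carry U+2010 in prefixes such as `HLA-A`.
#'
#' @return A list of class `pl_options`.
#' @export
#' @examples
#' pl_options(strict_percent_context = TRUE)
pl_options <- function(strict_percent_context = FALSE,
                       tolerate_whitespace = TRUE,
                       normalize_unicode_hyphens = TRUE) {
  structure(
    list(
      strict_percent_context = isTRUE(strict_percent_context),
      tolerate_whitespace = isTRUE(tolerate_whitespace),
      normalize_unicode_hyphens = isTRUE(normalize_unicode_hyphens)
    ),
    class = "pl_options"
  )
}

# Structured error: every user-facing failure carries a short machine code
# (e.g. GL_ONLY_DELIMITER) and, where known, a 0-based character position.
pl_abort <- function(code, message, position = NULL) {
  rlang::abort(
    message,
    class = c(paste0("plstring_error_", tolower(code)), "plstring_error"),
    code = code,
    position = position
  )
}

#' Extract the machine-readable code from a plstring error
#'
#' @param cnd A condition object caught from a `plstring_error`.
#' @return The short upper-case error code string, or `NA` if absent.
#' @export
pl_error_code <- function(cnd) {
  code <- cnd$code
  if (is.null(code)) NA_character_ else code
}

new_issue <- function(code, severity, message, position = NA_integer_) {
  tibble::tibble(
    code = code, severity = severity,
    message = message, position = as.integer(position)
  )
}

no_issues <- function() {
  tibble::tibble(
    code = character(), severity = character(),
    message = character(), position = integer()
  )
}

#' Build a validation report from a set of issues
#'
#' A report is valid when it contains no ERROR-severity issues; WARNING
#' issues are informational and leave `valid` `TRUE`.
#'
#' @param issues A tibble with columns `code`, `severity`, `message`,
#'   `position`.
#' @return A `pl_report` object.
#' @export
pl_report <- function(issues = no_issues()) {
  structure(
    list(valid = !any(issues$severity == "ERROR"), issues = issues),
    class = "pl_report"
  )
}

#' @export
print.pl_report <- function(x, ...) {
  status <- if (x$valid) "valid" else "INVALID"
  cat("<pl_report> ", status, ", ", nrow(x$issues), " issue(s)\n", sep = "")
  if (nrow(x$issues) > 0) print(x$issues)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a validation report into its issue table
#'
#' @param x A `pl_report`.
#' @param ... Unused.
#' @return A tibble with one row per issue.
#' @method tidy pl_report
#' @export
tidy.pl_report <- function(x, ...) x$issues

#' One-row summary of a validation report
#'
#' @param x A `pl_report`.
#' @param ... Unused.
#' @return A tibble with `valid`, `n_errors`, `n_warnings`.
#' @method glance pl_report
#' @export
glance.pl_report <- function(x, ...) {
  tibble::tibble(
    valid = x$valid,
    n_errors = sum(x$issues$severity == "ERROR"),
    n_warnings = sum(x$issues$severity == "WARNING")
  )
}
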