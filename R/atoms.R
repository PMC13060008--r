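# Atoms: the namespace-scoped leaves of a PL String (proteins, antigens,
# associated antigens, MACs, epitopes, match determinants).

EXPRESSION_SUFFIXES <- c("A", "C", "L", "N", "S", "Q")
PL_DELIMITERS <- c("+", "/", "~", "%")
GL_ONLY_DELIMITERS <- c("^", "|", "?")

normalize_hyphens <- function(x) {
  gsub("[\u2010\u2011\u2212]", "-", x)
}

#' Construct an atom from raw PL String text
#'
#' Records the surface spelling, strips an optional `HLA-` prefix, and notes
#' an expression-variant suffix (A, C, L, N, S, Q) or a dash marking a
#' proposed associated antigen. Classification against a vocabulary is done
#' separately by [pl_classify()].
#'
#' @param text Atom text as written (no delimiters, no whitespace).
#' @param normalize_unicode_hyphens Replace Unicode hyphens with ASCII `-`.
#' @return A `pl_atom` object.
#' @export
#' @examples
#' pl_atom("HLA-B*07:02")
#' pl_atom("A*24:09N")
pl_atom <- function(text, normalize_unicode_hyphens = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  norm <- if (normalize_unicode_hyphens) normalize_hyphens(text) else text
  if (!nzchar(norm)) pl_abort("EMPTY_INPUT", "atom text is empty")
  if (grepl("\\s", norm)) {
    pl_abort("ATOM_WHITESPACE", sprintf("atom '%s' contains whitespace", norm))
  }
  bad <- intersect(strsplit(norm, "")[[1]],
                   c(PL_DELIMITERS, GL_ONLY_DELIMITERS, "#"))
  if (length(bad) > 0) {
    pl_abort("BAD_ATOM",
             sprintf("atom '%s' contains reserved character '%s'", norm, bad[1]))
  }
  prefix <- grepl("^HLA-", norm)
  if (prefix) norm <- sub("^HLA-", "", norm)
  # expression suffix: a trailing A/C/L/N/S/Q directly after the last numeric
  # field of a molecular designation (e.g. A*24:09N)
  suffix <- NA_character_
  if (grepl("\\*", norm) && grepl("[0-9][ACLNSQ]$", norm)) {
    suffix <- substr(norm, nchar(norm), nchar(norm))
  }
  proposed <- grepl("^[A-Za-z]+-[0-9]", norm)
  structure(
    list(
      raw_text = raw,
      normalized_text = norm,
      prefix_present = prefix,
      expression_suffix = suffix,
      proposed = proposed,
      atom_class = NA_character_,
      locus = NA_character_,
      chain_role = NA_character_,
      partner_loci = character()
    ),
    class = "pl_atom"
  )
}

#' @export
print.pl_atom <- function(x, ...) {
  cls <- if (is.na(x$atom_class)) "unclassified" else x$atom_class
  cat("<pl_atom> ", x$normalized_text, " [", cls, "]\n", sep = "")
  invisible(x)
}

#' @export
format.pl_atom <- function(x, ...) x$normalized_text

# Strip an expression suffix for suffix-insensitive comparison/lookup.
strip_expression_suffix <- function(text) {
  if (grepl("\\*", text) && grepl("[0-9][ACLNSQ]$", text)) {
    substr(text, 1L, nchar(text) - 1L)
  } else {
    text
  }
}
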