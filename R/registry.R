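# Governed namespaces and their vocabularies.
#
# The grammar is agnostic to the vocabulary it transmits: which atoms are
# permissible is decided by the governing authority of a namespace (WHO,
# OPTN, ET, NMDP). This module manages namespace descriptors, loads
# versioned vocabulary and MAC tables from TSV, classifies atoms, expands
# multiple allele codes, and enforces alpha/beta heterodimer pairing.

ATOM_CLASSES <- c("PROTEIN", "ANTIGEN", "ASSOCIATED_ANTIGEN", "MAC",
                  "EPITOPE", "MATCH_DETERMINANT")

builtin_namespaces <- function() {
  tibble::tibble(
    id = c("et", "nmdp", "optn", "who"),
    authority_name = c(
      "Eurotransplant Reference Laboratory",
      "NMDP",
      "Organ Procurement and Transplantation Network",
      "WHO Nomenclature Committee for Factors of the HLA System"
    ),
    governance_url = c(
      "etrl.eurotransplant.org/resources/hla-tables/",
      "hml.nmdp.org/MacUI/",
      "optn.transplant.hrsa.gov/policies-bylaws/policies/",
      "www.ebi.ac.uk/ipd/imgt/hla/"
    ),
    builtin = TRUE
  )
}

the_registry <- new.env(parent = emptyenv())

registry_table <- function() {
  if (is.null(the_registry$extra)) the_registry$extra <- builtin_namespaces()[0, ]
  dplyr::bind_rows(builtin_namespaces(), the_registry$extra)
}

#' List registered PLSC namespaces
#'
#' The built-in registry holds exactly the four governed namespaces recorded
#' in PLSCs as `et`, `nmdp`, `optn` and `who`, plus any extensions added
#' with [pl_register_namespace()].
#'
#' @return A tibble with columns `id`, `authority_name`, `governance_url`,
#'   `builtin`.
#' @export
#' @examples
#' pl_namespaces()
pl_namespaces <- function() registry_table()

#' Register an extension namespace
#'
#' A new namespace is admitted only when its governing body attests to all
#' four requirements placed on namespace authorities: governance,
#' transparency, compatibility with the PL String syntax, and version
#' control.
#'
#' @param id Lower-case namespace token.
#' @param authority_name Human-readable authority name.
#' @param governance_url Where the vocabulary is documented.
#' @param governance,transparency,compatibility,version_control The four
#'   attestation flags; all must be `TRUE`.
#' @return The updated registry tibble, invisibly.
#' @export
pl_register_namespace <- function(id, authority_name, governance_url = "",
                                  governance = FALSE, transparency = FALSE,
                                  compatibility = FALSE, version_control = FALSE) {
  if (!grepl("^[a-z][a-z0-9]*$", id)) {
    pl_abort("UNKNOWN_NAMESPACE", "namespace id must be a lower-case token")
  }
  if (id %in% registry_table()$id) {
    pl_abort("UNKNOWN_NAMESPACE", sprintf("namespace '%s' already registered", id))
  }
  if (!all(governance, transparency, compatibility, version_control)) {
    pl_abort("ATTESTATION_MISSING",
             "all four attestations (governance, transparency, compatibility, version control) are required")
  }
  the_registry$extra <- dplyr::bind_rows(
    the_registry$extra,
    tibble::tibble(id = id, authority_name = authority_name,
                   governance_url = governance_url, builtin = FALSE)
  )
  invisible(registry_table())
}

#' Reset the namespace registry to the four built-ins
#' @return The registry tibble, invisibly.
#' @export
pl_reset_namespaces <- function() {
  the_registry$extra <- builtin_namespaces()[0, ]
  invisible(registry_table())
}

version_token_ok <- function(token) {
  grepl("^[0-9]+\\.[0-9]+\\.[0-9]+$", token) ||
    (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", token) &&
       !is.na(as.Date(token, format = "%Y-%m-%d")))
}

#' Load a namespace vocabulary from TSV
#'
#' Vocabulary files are tab-separated with one comment line
#' `#namespace=<id> version=<token>` followed by a header
#' `atom  class  locus  chain_role  partner_loci` (partner loci separated by
#' `|`). Bundled example vocabularies live under
#' `system.file("extdata", package = "plstring")`; authoritative tables are
#' supplied by the user through this same loader, since vocabulary content
#' is governed by each namespace's authority, not by this package.
#'
#' @param path Path to a vocabulary TSV file.
#' @return A `pl_vocabulary`: list with `namespace_id`, `version_token` and
#'   an `entries` tibble.
#' @export
#' @examples
#' vocab <- pl_load_vocabulary(system.file("extdata", "who.tsv", package = "plstring"))
#' vocab$namespace_id
pl_load_vocabulary <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L || !grepl("^#namespace=", lines[1])) {
    pl_abort("BAD_HEADER",
             "vocabulary file must start with '#namespace=<id> version=<token>'")
  }
  meta <- regmatches(lines[1],
                     regexec("^#namespace=([a-z0-9]+)\\s+version=(\\S+)\\s*$", lines[1]))[[1]]
  if (length(meta) != 3L) pl_abort("BAD_HEADER", "malformed namespace/version comment line")
  ns <- meta[2]; version <- meta[3]
  if (!version_token_ok(version)) {
    pl_abort("BAD_VERSION_TOKEN",
             sprintf("'%s' is neither a release (x.y.z) nor an ISO date", version))
  }
  header <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  expected <- c("atom", "class", "locus", "chain_role", "partner_loci")
  if (!identical(header, expected)) {
    pl_abort("BAD_HEADER", paste0("expected header: ", paste(expected, collapse = "\t")))
  }
  body <- lines[-(1:2)]
  if (length(body) == 0L) {
    entries <- tibble::tibble(atom = character(), class = character(),
                              locus = character(), chain_role = character(),
                              partner_loci = list())
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2L | lengths(fields) > 5L)
    if (length(bad) > 0) {
      pl_abort("BAD_HEADER", sprintf("row %d does not have 5 tab-separated fields", bad[1]))
    }
    # strsplit drops trailing empty fields; pad back to 5
    fields <- lapply(fields, function(f) {
      length(f) <- 5L
      f[is.na(f)] <- ""
      f
    })
    m <- do.call(rbind, fields)
    entries <- tibble::tibble(
      atom = normalize_hyphens(m[, 1]),
      class = m[, 2],
      locus = ifelse(m[, 3] == "", NA_character_, m[, 3]),
      chain_role = ifelse(m[, 4] == "", "NONE", m[, 4]),
      partner_loci = lapply(m[, 5], function(p) {
        if (!nzchar(p)) character() else strsplit(p, "|", fixed = TRUE)[[1]]
      })
    )
  }
  if (anyDuplicated(entries$atom)) {
    pl_abort("DUPLICATE_ATOM",
             sprintf("duplicate vocabulary atom '%s'",
                     entries$atom[duplicated(entries$atom)][1]))
  }
  if (!all(entries$class %in% ATOM_CLASSES)) {
    bad <- setdiff(unique(entries$class), ATOM_CLASSES)
    pl_abort("BAD_HEADER", sprintf("unknown atom class '%s'", bad[1]))
  }
  bad_pair <- entries$chain_role %in% c("ALPHA", "BETA") & lengths(entries$partner_loci) == 0
  if (any(bad_pair)) {
    pl_abort("BAD_HEADER",
             sprintf("atom '%s' has a chain role but no partner loci",
                     entries$atom[bad_pair][1]))
  }
  structure(list(namespace_id = ns, version_token = version, entries = entries),
            class = "pl_vocabulary")
}

#' @export
print.pl_vocabulary <- function(x, ...) {
  cat("<pl_vocabulary> ", x$namespace_id, " @ ", x$version_token, ", ",
      nrow(x$entries), " atoms\n", sep = "")
  invisible(x)
}

#' Load a bundled example vocabulary by namespace id
#'
#' Convenience wrapper around [pl_load_vocabulary()] for the small example
#' vocabularies shipped with the package. These cover the atoms used in the
#' worked examples and tests; they are illustrative, not authoritative.
#'
#' @param namespace_id One of `"who"`, `"optn"`, `"et"`, `"nmdp"`.
#' @return A `pl_vocabulary`.
#' @export
pl_example_vocabulary <- function(namespace_id = c("who", "optn", "et", "nmdp")) {
  namespace_id <- match.arg(namespace_id)
  pl_load_vocabulary(system.file("extdata", paste0(namespace_id, ".tsv"),
                                 package = "plstring", mustWork = TRUE))
}

# Look up an atom's vocabulary entry; prefix and expression-suffix spellings
# resolve to the same entry. Returns a one-row tibble or NULL.
vocab_lookup <- function(vocab, normalized_text) {
  e <- vocab$entries
  hit <- which(e$atom == normalized_text)
  if (length(hit) == 0L) {
    stripped <- strip_expression_suffix(normalized_text)
    if (stripped != normalized_text) {
      hit <- which(e$atom == stripped)
    } else if (grepl("\\*", normalized_text)) {
      # bare spelling of an entry recorded with its expression suffix
      hit <- which(vapply(e$atom, strip_expression_suffix, character(1)) ==
                     normalized_text)
    }
  }
  if (length(hit) == 0L) NULL else e[hit[1], ]
}

#' Classify an atom against a vocabulary
#'
#' Fills `atom_class`, `locus`, `chain_role` and `partner_loci` from the
#' vocabulary. Spellings with and without the `HLA-` prefix classify
#' identically, as do spellings with and without an expression-variant
#' suffix (`A*24:09` and `A*24:09N` resolve to one entry).
#'
#' @param atom A `pl_atom` (or atom text, which is coerced).
#' @param vocab A `pl_vocabulary`.
#' @return The atom with classification fields filled.
#' @export
#' @examples
#' vocab <- pl_example_vocabulary("who")
#' pl_classify("HLA-B*07:02", vocab)$atom_class
pl_classify <- function(atom, vocab) {
  if (is.character(atom)) atom <- pl_atom(atom)
  entry <- vocab_lookup(vocab, atom$normalized_text)
  if (is.null(entry)) {
    pl_abort("UNKNOWN_ATOM",
             sprintf("atom '%s' is not in the %s vocabulary (version %s)",
                     atom$normalized_text, vocab$namespace_id, vocab$version_token))
  }
  atom$atom_class <- entry$class
  atom$locus <- entry$locus
  atom$chain_role <- entry$chain_role
  atom$partner_loci <- entry$partner_loci[[1]]
  atom
}

mac_shape <- function(text) {
  regmatches(text, regexec("^([A-Z0-9]+)\\*([0-9]+):([A-Z]{2,})$", text))[[1]]
}

#' Load a multiple allele code (MAC) table from TSV
#'
#' MAC tables are tab-separated with one comment line
#' `#version=<token>` followed by a header `code  expansion`; the expansion
#' field lists two or more designations separated by `|`, either bare
#' second fields (applied within the MAC's first field, e.g. `01|02`) or
#' full protein names containing `*`.
#'
#' @param path Path to a MAC TSV file.
#' @return A `pl_mac_table`: list with `version_token` and a `codes` tibble.
#' @export
pl_load_mac_table <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L || !grepl("^#version=", lines[1])) {
    pl_abort("BAD_HEADER", "MAC table must start with '#version=<token>'")
  }
  version <- sub("^#version=", "", trimws(lines[1]))
  if (!version_token_ok(version)) {
    pl_abort("BAD_VERSION_TOKEN", sprintf("bad MAC table version '%s'", version))
  }
  if (!identical(strsplit(lines[2], "\t", fixed = TRUE)[[1]], c("code", "expansion"))) {
    pl_abort("BAD_HEADER", "expected header: code\texpansion")
  }
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  codes <- tibble::tibble(
    code = vapply(body, `[`, character(1), 1L),
    expansion = lapply(body, function(f) strsplit(f[2], "|", fixed = TRUE)[[1]])
  )
  if (anyDuplicated(codes$code)) pl_abort("DUPLICATE_ATOM", "duplicate MAC code")
  if (any(lengths(codes$expansion) < 2L)) {
    pl_abort("MALFORMED_MAC_TABLE", "every MAC expansion must list >= 2 designations")
  }
  structure(list(version_token = version, codes = codes), class = "pl_mac_table")
}

#' Bundled example MAC table
#' @return A `pl_mac_table`.
#' @export
pl_example_mac_table <- function() {
  pl_load_mac_table(system.file("extdata", "mac.tsv", package = "plstring",
                                mustWork = TRUE))
}

#' Expand a multiple allele code into an XOR expression
#'
#' A MAC atom such as `A*02:AB` stands for exactly one of a defined set of
#' proteins; expansion yields the equivalent `/`-joined exclusive-OR
#' expression (`A*02:01/A*02:02`).
#'
#' @param atom A `pl_atom` (or atom text) of shape `locus*group:CODE` with an
#'   alphabetic code.
#' @param mac A `pl_mac_table`.
#' @return A `pl_expr` XOR node over the expanded protein atoms.
#' @export
#' @examples
#' pl_serialize(pl_expand_mac("A*02:AB", pl_example_mac_table()))
pl_expand_mac <- function(atom, mac) {
  if (is.character(atom)) atom <- pl_atom(atom)
  m <- mac_shape(atom$normalized_text)
  if (length(m) != 4L) {
    pl_abort("NOT_A_MAC",
             sprintf("'%s' does not have MAC shape locus*group:CODE",
                     atom$normalized_text))
  }
  locus <- m[2]; group <- m[3]; code <- m[4]
  hit <- which(mac$codes$code == code)
  if (length(hit) == 0L) {
    pl_abort("UNKNOWN_MAC", sprintf("MAC code '%s' is not in the table", code))
  }
  expansion <- mac$codes$expansion[[hit[1]]]
  if (length(expansion) < 2L) pl_abort("MALFORMED_MAC_TABLE", "expansion too small")
  names_full <- ifelse(grepl("\\*", expansion), expansion,
                       paste0(locus, "*", group, ":", expansion))
  new_expr("XOR", children = lapply(names_full, function(t) {
    new_expr("ATOM", atom = pl_atom(t))
  }))
}

#' Validate a heterodimer pairing
#'
#' A `~` may only link one alpha-chain atom with one beta-chain atom whose
#' loci the namespace pairs (for example DQA1 with DQB1), in either written
#' order.
#'
#' @param left,right `pl_atom`s or atom texts.
#' @param vocab A `pl_vocabulary`.
#' @return A `pl_report`.
#' @export
#' @examples
#' vocab <- pl_example_vocabulary("who")
#' pl_check_heterodimer("DQA1*05:01", "DQB1*02:01", vocab)$valid
pl_check_heterodimer <- function(left, right, vocab) {
  issues <- no_issues()
  classify_or_issue <- function(a) {
    if (is.character(a)) a <- pl_atom(a)
    tryCatch(pl_classify(a, vocab), plstring_error = function(cnd) {
      issues <<- dplyr::bind_rows(issues, new_issue("UNKNOWN_ATOM", "ERROR",
                                                    conditionMessage(cnd)))
      NULL
    })
  }
  l <- classify_or_issue(left)
  r <- classify_or_issue(right)
  if (is.null(l) || is.null(r)) return(pl_report(issues))
  roles <- c(l$chain_role, r$chain_role)
  if (any(roles == "NONE")) {
    who <- c(l$normalized_text, r$normalized_text)[roles == "NONE"][1]
    issues <- dplyr::bind_rows(issues, new_issue(
      "NOT_HETERODIMERIC", "ERROR",
      sprintf("'%s' is not an alpha- or beta-chain specificity", who)
    ))
  } else if (roles[1] == roles[2]) {
    issues <- dplyr::bind_rows(issues, new_issue(
      "SAME_CHAIN", "ERROR",
      sprintf("'%s' and '%s' are both %s chains", l$normalized_text,
              r$normalized_text, tolower(roles[1]))
    ))
  } else {
    ok <- (l$locus %in% r$partner_loci) && (r$locus %in% l$partner_loci)
    if (!ok) {
      issues <- dplyr::bind_rows(issues, new_issue(
        "LOCUS_MISMATCH", "ERROR",
        sprintf("loci %s and %s are not a recognised alpha/beta pairing",
                l$locus, r$locus)
      ))
    }
  }
  pl_report(issues)
}

#' Validate a parsed expression against a namespace vocabulary
#'
#' Walks the tree in pre-order, classifying every atom, checking heterodimer
#' alpha/beta pairings, flagging `%` applied to protein-level operands, and
#' warning on duplicate operands of one node.
#'
#' @param expr A `pl_expr` or a PL String (which is parsed first).
#' @param vocab A `pl_vocabulary`.
#' @param options A [pl_options()] list.
#' @return A `pl_report`.
#' @export
#' @examples
#' vocab <- pl_example_vocabulary("optn")
#' pl_validate("A2+A68+A69+B57+B58", vocab)$valid
pl_validate <- function(expr, vocab, options = pl_options()) {
  if (is.character(expr)) expr <- pl_parse(expr, options)
  issues <- no_issues()
  add <- function(...) issues <<- dplyr::bind_rows(issues, new_issue(...))
  walk <- function(e) {
    if (e$node_kind == "ATOM") {
      tryCatch(pl_classify(e$atom, vocab), plstring_error = function(cnd) {
        add("UNKNOWN_ATOM", "ERROR", conditionMessage(cnd))
      })
      return(invisible(NULL))
    }
    if (e$node_kind == "HETERODIMER") {
      rep <- pl_check_heterodimer(e$children[[1]]$atom, e$children[[2]]$atom, vocab)
      issues <<- dplyr::bind_rows(issues, rep$issues)
      return(invisible(NULL))
    }
    if (e$node_kind == "IOR" &&
        any(vapply(e$children, protein_shaped, logical(1)))) {
      add("PERCENT_CONTEXT",
          if (options$strict_percent_context) "ERROR" else "WARNING",
          "'%' is documented for antigens but is applied here to protein-level operands")
    }
    texts <- vapply(e$children, serialize_rec, character(1), canonical = TRUE)
    if (anyDuplicated(texts)) {
      add("DUPLICATE_OPERAND", "WARNING",
          sprintf("operand '%s' appears more than once under one %s node",
                  texts[duplicated(texts)][1], e$node_kind))
    }
    lapply(e$children, walk)
    invisible(NULL)
  }
  walk(expr)
  pl_report(issues)
}
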