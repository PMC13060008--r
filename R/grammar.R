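# PL String grammar: tokenizer, recursive-descent parser, serializer.
#
# The grammar has no grouping construct, so the token stream is flat and the
# parser is a cascade of splits by binding tightness. Binding order
# (tightest -> loosest) is ~, /, %, + — derived from the published worked
# examples; the printed precedence integers of the delimiter table are kept
# verbatim as metadata in pl_operators().

#' Delimiter metadata for the PL String grammar
#'
#' The four PL String delimiters with their operation names, application
#' contexts, the precedence integers as printed in the grammar's delimiter
#' table, and the binding rank actually used by the parser (1 = binds
#' tightest).
#'
#' @return A tibble with columns `symbol`, `operation`, `context`,
#'   `published_precedence`, `binding_rank`.
#' @export
#' @examples
#' pl_operators()
pl_operators <- function() {
  tibble::tibble(
    symbol = c("+", "~", "%", "/"),
    operation = c("AND", "Heterodimer", "Inclusive OR", "Exclusive OR"),
    context = c("All", "All", "Antigens", "Antigens; Proteins"),
    published_precedence = c(1L, 2L, 3L, 4L),
    binding_rank = c(4L, 1L, 3L, 2L)
  )
}

#' Delimiter comparison between GL Strings and PL Strings
#'
#' All seven delimiters used across the genotype list (GL) and phenotype
#' list (PL) String grammars, and which grammar admits each. GL Strings use
#' six delimiters; PL Strings use four, of which `%` is PL-only and `^`,
#' `|`, `?` are GL-only.
#'
#' @return A tibble with columns `symbol`, `name`, `operation`, `gl`, `pl`.
#' @export
pl_gl_delimiters <- function() {
  tibble::tibble(
    symbol = c("+", "/", "~", "%", "^", "|", "?"),
    name = c("Plus sign", "Forward slash", "Tilde", "Percent sign",
             "Caret", "Pipe", "Question mark"),
    operation = c("AND", "Exclusive OR",
                  "Chromosomal phase (GL) / heterodimer membership (PL)",
                  "Inclusive OR", "AND (unphased individual loci)",
                  "OR (genotypes)", "Locus ambiguity"),
    gl = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    pl = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

op_kind <- function(symbol) {
  switch(symbol,
    "+" = "OP_PLUS", "/" = "OP_SLASH", "~" = "OP_TILDE", "%" = "OP_PERCENT"
  )
}

#' Tokenize PL String text
#'
#' Splits text into alternating atom and delimiter tokens. Unicode hyphens
#' are normalized, whitespace around delimiters is stripped, and the GL
#' String-only delimiters `^`, `|`, `?` as well as the PLSC `#` separator
#' are rejected with structured errors.
#'
#' @param text A single PL String.
#' @param options A [pl_options()] list.
#' @return A tibble of tokens with columns `kind`, `text`, `start` (0-based
#'   offset in the normalized input, which is also returned as attribute
#'   `normalized`).
#' @export
#' @examples
#' pl_tokenize("A2+B7")
#' pl_tokenize("DPA1*01:03 ~ DPB1*06:01")
pl_tokenize <- function(text, options = pl_options()) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- if (options$normalize_unicode_hyphens) normalize_hyphens(text) else text
  raw <- trimws(raw)
  if (!nzchar(raw)) pl_abort("EMPTY_INPUT", "PL String is empty")

  chars <- strsplit(raw, "")[[1]]
  hash <- which(chars == "#")
  if (length(hash) > 0) {
    pl_abort(
      "PLSC_IN_PLSTRING",
      paste0("'#' is the PLSC separator, not a PL String delimiter; ",
             "use pl_decode() for PL String Codes"),
      position = hash[1] - 1L
    )
  }
  gl_hit <- which(chars %in% GL_ONLY_DELIMITERS)
  if (length(gl_hit) > 0) {
    pl_abort(
      "GL_ONLY_DELIMITER",
      sprintf("'%s' is a GL String-only delimiter and is not valid in a PL String",
              chars[gl_hit[1]]),
      position = gl_hit[1] - 1L
    )
  }

  is_delim <- chars %in% PL_DELIMITERS
  bounds <- c(0L, which(is_delim), length(chars) + 1L)
  segments <- character(length(bounds) - 1L)
  for (i in seq_along(segments)) {
    lo <- bounds[i] + 1L
    hi <- bounds[i + 1L] - 1L
    segments[i] <- if (lo > hi) "" else paste(chars[lo:hi], collapse = "")
  }
  delims <- chars[is_delim]

  atoms <- if (options$tolerate_whitespace) trimws(segments) else segments
  if (any(!nzchar(atoms))) {
    pl_abort("DANGLING_OPERATOR",
             "PL String has a leading, trailing or doubled delimiter")
  }
  if (any(grepl("\\s", atoms))) {
    bad <- atoms[grepl("\\s", atoms)][1]
    pl_abort("ATOM_WHITESPACE",
             sprintf("atom '%s' contains interior whitespace", bad))
  }

  kinds <- character(0)
  texts <- character(0)
  for (i in seq_along(atoms)) {
    kinds <- c(kinds, "ATOM_TEXT")
    texts <- c(texts, atoms[i])
    if (i <= length(delims)) {
      kinds <- c(kinds, op_kind(delims[i]))
      texts <- c(texts, delims[i])
    }
  }
  starts <- c(0L, cumsum(nchar(texts)))[seq_along(texts)]
  out <- tibble::tibble(kind = kinds, text = texts, start = starts)
  attr(out, "normalized") <- paste(texts, collapse = "")
  out
}

new_expr <- function(kind, children = list(), atom = NULL) {
  structure(list(node_kind = kind, children = children, atom = atom),
            class = "pl_expr")
}

# Split a vector of atom texts + interleaved delimiters at one symbol.
# `items` is the token tibble subset (a contiguous run); returns list of runs.
split_on <- function(tokens, symbol) {
  idx <- which(tokens$kind != "ATOM_TEXT" & tokens$text == symbol)
  if (length(idx) == 0) return(list(tokens))
  bounds <- c(0L, idx, nrow(tokens) + 1L)
  out <- vector("list", length(bounds) - 1L)
  for (i in seq_along(out)) {
    out[[i]] <- tokens[(bounds[i] + 1L):(bounds[i + 1L] - 1L), ]
  }
  out
}

parse_level <- function(tokens, level, options) {
  # level order loosest -> tightest: + (AND), % (IOR), / (XOR), ~ (HET)
  ops <- c("+", "%", "/", "~")
  kinds <- c("AND", "IOR", "XOR", "HETERODIMER")
  if (level > length(ops)) {
    stopifnot(nrow(tokens) == 1L, tokens$kind == "ATOM_TEXT")
    return(new_expr("ATOM", atom = pl_atom(tokens$text,
      normalize_unicode_hyphens = FALSE)))
  }
  parts <- split_on(tokens, ops[level])
  if (length(parts) == 1L) return(parse_level(tokens, level + 1L, options))
  if (ops[level] == "~") {
    if (length(parts) > 2L) {
      pl_abort("HETERODIMER_ARITY",
               "only two elements can be linked by '~'",
               position = tokens$start[tokens$text == "~"][2])
    }
    children <- lapply(parts, function(p) {
      if (nrow(p) != 1L || p$kind[1] != "ATOM_TEXT") {
        pl_abort("HETERODIMER_OPERAND",
                 "'~' operands must be single alpha/beta atoms")
      }
      parse_level(p, level + 1L, options)
    })
    return(new_expr("HETERODIMER", children = children))
  }
  children <- lapply(parts, parse_level, level = level + 1L, options = options)
  new_expr(kinds[level], children = children)
}

# Shape heuristic used before any vocabulary is attached: molecular
# (protein-level) designations carry '*'.
protein_shaped <- function(expr) {
  if (expr$node_kind == "ATOM") return(grepl("\\*", expr$atom$normalized_text))
  if (expr$node_kind == "HETERODIMER") {
    return(any(vapply(expr$children, protein_shaped, logical(1))))
  }
  FALSE
}

percent_context_issues <- function(expr) {
  issues <- no_issues()
  walk <- function(e) {
    if (e$node_kind == "IOR" && any(vapply(e$children, protein_shaped, logical(1)))) {
      issues <<- dplyr::bind_rows(issues, new_issue(
        "PERCENT_CONTEXT", "WARNING",
        "'%' is documented for antigens but is applied here to protein-level operands"
      ))
    }
    if (e$node_kind != "ATOM") lapply(e$children, walk)
    invisible(NULL)
  }
  walk(expr)
  issues
}

#' Parse a PL String into an expression tree
#'
#' Produces a recursive expression over `AND` (`+`), `XOR` (`/`), `IOR`
#' (`%`) and `HETERODIMER` (`~`) nodes with atoms at the leaves. Chains of
#' one associative delimiter are flattened to a single n-ary node;
#' tilde-chains of three or more atoms are an arity error because a
#' heterodimer has exactly one alpha and one beta constituent.
#'
#' @param text A single PL String.
#' @param options A [pl_options()] list; with `strict_percent_context = TRUE`
#'   a `%` applied to protein-level operands is an error.
#' @return A `pl_expr` tree.
#' @export
#' @examples
#' pl_parse("HLA-A*01:01/HLA-A*01:02+HLA-A*02:01")
#' pl_parse("A2+A68+A69+B57+B58")
pl_parse <- function(text, options = pl_options()) {
  tokens <- pl_tokenize(text, options)
  expr <- parse_level(tokens, 1L, options)
  if (options$strict_percent_context) {
    iss <- percent_context_issues(expr)
    if (nrow(iss) > 0) {
      pl_abort("PERCENT_CONTEXT", iss$message[1])
    }
  }
  expr
}

#' @export
print.pl_expr <- function(x, ...) {
  cat("<pl_expr> ", pl_serialize(x), "\n", sep = "")
  cat(describe_expr(x, indent = 0L))
  invisible(x)
}

describe_expr <- function(e, indent) {
  pad <- strrep("  ", indent)
  if (e$node_kind == "ATOM") {
    return(paste0(pad, "ATOM ", e$atom$normalized_text, "\n"))
  }
  paste0(pad, e$node_kind, "\n",
         paste(vapply(e$children, describe_expr, character(1),
                      indent = indent + 1L), collapse = ""))
}

expr_atoms <- function(expr) {
  if (expr$node_kind == "ATOM") return(list(expr$atom))
  unlist(lapply(expr$children, expr_atoms), recursive = FALSE)
}

#' Flatten an expression tree to a tibble of atoms
#'
#' @param x A `pl_expr`.
#' @param ... Unused.
#' @return A tibble with one row per leaf atom, in written order.
#' @method tidy pl_expr
#' @export
tidy.pl_expr <- function(x, ...) {
  atoms <- expr_atoms(x)
  tibble::tibble(
    text = vapply(atoms, function(a) a$normalized_text, character(1)),
    raw_text = vapply(atoms, function(a) a$raw_text, character(1)),
    prefix_present = vapply(atoms, function(a) a$prefix_present, logical(1)),
    expression_suffix = vapply(atoms, function(a) a$expression_suffix, character(1)),
    proposed = vapply(atoms, function(a) a$proposed, logical(1)),
    atom_class = vapply(atoms, function(a) a$atom_class, character(1)),
    locus = vapply(atoms, function(a) a$locus, character(1))
  )
}

check_expr_invariants <- function(expr) {
  if (!inherits(expr, "pl_expr")) pl_abort("INVALID_TREE", "not a pl_expr")
  k <- expr$node_kind
  if (!k %in% c("ATOM", "HETERODIMER", "AND", "XOR", "IOR")) {
    pl_abort("INVALID_TREE", sprintf("unknown node kind '%s'", k))
  }
  if (k == "ATOM") {
    if (!inherits(expr$atom, "pl_atom")) {
      pl_abort("INVALID_TREE", "ATOM node without atom")
    }
    return(invisible(TRUE))
  }
  if (k == "HETERODIMER") {
    if (length(expr$children) != 2L ||
        !all(vapply(expr$children, function(c) c$node_kind == "ATOM", logical(1)))) {
      pl_abort("INVALID_TREE", "HETERODIMER must have exactly two ATOM children")
    }
  } else {
    if (length(expr$children) < 2L) {
      pl_abort("INVALID_TREE", sprintf("%s must have >= 2 children", k))
    }
    if (any(vapply(expr$children, function(c) c$node_kind == k, logical(1)))) {
      pl_abort("INVALID_TREE", sprintf("%s child of %s is not flattened", k, k))
    }
  }
  lapply(expr$children, check_expr_invariants)
  invisible(TRUE)
}

het_child_order <- function(children) {
  roles <- vapply(children, function(c) c$atom$chain_role, character(1))
  if (!any(is.na(roles)) && setequal(roles, c("ALPHA", "BETA"))) {
    order(match(roles, c("ALPHA", "BETA")))
  } else {
    order(vapply(children, pl_serialize, character(1)))
  }
}

#' Serialize an expression tree back to PL String text
#'
#' Non-canonical serialization preserves the written operand order. Canonical
#' serialization sorts operands of every node by their serialized text —
#' alpha chain first inside heterodimers when chain roles are known — giving
#' a unique representative per ordinal-freedom equivalence class.
#'
#' @param expr A `pl_expr`.
#' @param canonical Sort operands canonically.
#' @return A single PL String.
#' @export
#' @examples
#' pl_serialize(pl_parse("B7+A2"), canonical = TRUE)
pl_serialize <- function(expr, canonical = FALSE) {
  check_expr_invariants(expr)
  serialize_rec(expr, canonical)
}

serialize_rec <- function(expr, canonical) {
  k <- expr$node_kind
  if (k == "ATOM") return(expr$atom$normalized_text)
  sym <- c(AND = "+", XOR = "/", IOR = "%", HETERODIMER = "~")[[k]]
  parts <- vapply(expr$children, serialize_rec, character(1), canonical = canonical)
  if (canonical) {
    if (k == "HETERODIMER") {
      parts <- parts[het_child_order(expr$children)]
    } else {
      parts <- sort(parts, method = "radix")
    }
  }
  paste(parts, collapse = sym)
}

#' Structural equality of two expression trees
#'
#' Compares node kinds and atom spellings; with `ignore_order = TRUE`
#' operand order is disregarded (ordinal freedom), via canonical
#' serialization.
#'
#' @param a,b `pl_expr` trees.
#' @param ignore_order Compare up to operand permutation.
#' @return `TRUE` or `FALSE`.
#' @export
pl_expr_equal <- function(a, b, ignore_order = FALSE) {
  pl_serialize(a, canonical = ignore_order) ==
    pl_serialize(b, canonical = ignore_order)
}

#' Report GL String-only delimiters in a piece of text
#'
#' Scans text for the three GL String-only delimiters (`^`, `|`, `?`),
#' reported as errors, and for `/`, which both grammars share, reported as
#' an informational note. The input is never modified.
#'
#' @param text Text to scan (need not be a valid PL String).
#' @return A `pl_report`.
#' @export
#' @examples
#' pl_lint_gl("A*01:01+B*07:02|B*08:01")
pl_lint_gl <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(normalize_hyphens(text), "")[[1]]
  issues <- no_issues()
  for (i in seq_along(chars)) {
    if (chars[i] %in% GL_ONLY_DELIMITERS) {
      issues <- dplyr::bind_rows(issues, new_issue(
        "GL_ONLY_DELIMITER", "ERROR",
        sprintf("'%s' is a GL String-only delimiter", chars[i]),
        position = i - 1L
      ))
    } else if (chars[i] == "/") {
      issues <- dplyr::bind_rows(issues, new_issue(
        "SHARED_GL_DELIMITER", "WARNING",
        "'/' has the same exclusive-OR meaning in GL and PL Strings",
        position = i - 1L
      ))
    }
  }
  pl_report(issues)
}
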