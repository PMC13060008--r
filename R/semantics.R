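# Possible-phenotype ("worlds") semantics.
#
# A PL String denotes a set of possible phenotype worlds, each a set of
# molecules (single specificities or alpha~beta heterodimers):
#   atom / heterodimer  -> one world holding that one molecule
#   AND(c1..ck)         -> all unions of one world per child
#   XOR(c1..ck)         -> exactly one child realised: union of child worlds
#   IOR(c1..ck)         -> any non-empty subset of children realised
# Worlds are sets; duplicates arising from shared molecules are merged.

molecule_key <- function(expr) {
  if (expr$node_kind == "ATOM") return(expr$atom$normalized_text)
  # heterodimer: unordered pair, alpha-first when chain roles are known
  parts <- vapply(expr$children, function(c) c$atom$normalized_text, character(1))
  roles <- vapply(expr$children, function(c) c$atom$chain_role, character(1))
  if (!any(is.na(roles)) && setequal(roles, c("ALPHA", "BETA"))) {
    parts <- parts[order(match(roles, c("ALPHA", "BETA")))]
  } else {
    parts <- sort(parts, method = "radix")
  }
  paste(parts, collapse = "~")
}

world_key <- function(world) paste(world, collapse = " + ")

dedup_worlds <- function(worlds) {
  keys <- vapply(worlds, world_key, character(1))
  worlds <- worlds[!duplicated(keys)]
  worlds[order(vapply(worlds, world_key, character(1)), method = "radix")]
}

cross_union <- function(a, b, max_worlds) {
  if (length(a) * length(b) > max_worlds) {
    pl_abort("EXPANSION_TOO_LARGE",
             sprintf("expansion exceeds the %d-world cap", max_worlds))
  }
  out <- vector("list", length(a) * length(b))
  k <- 0L
  for (wa in a) for (wb in b) {
    k <- k + 1L
    out[[k]] <- sort(unique(c(wa, wb)), method = "radix")
  }
  dedup_worlds(out)
}

worlds_rec <- function(expr, max_worlds) {
  k <- expr$node_kind
  if (k %in% c("ATOM", "HETERODIMER")) {
    return(list(molecule_key(expr)))
  }
  child_worlds <- lapply(expr$children, worlds_rec, max_worlds = max_worlds)
  if (k == "AND") {
    return(Reduce(function(a, b) cross_union(a, b, max_worlds), child_worlds))
  }
  if (k == "XOR") {
    return(dedup_worlds(unlist(child_worlds, recursive = FALSE)))
  }
  # IOR: every non-empty subset of children, one world from each member
  n <- length(child_worlds)
  if (2^n - 1 > max_worlds) {
    pl_abort("EXPANSION_TOO_LARGE",
             sprintf("expansion exceeds the %d-world cap", max_worlds))
  }
  out <- list()
  for (mask in seq_len(2L^n - 1L)) {
    live <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    sub <- Reduce(function(a, b) cross_union(a, b, max_worlds),
                  child_worlds[live])
    out <- c(out, sub)
    if (length(out) > max_worlds) {
      pl_abort("EXPANSION_TOO_LARGE",
               sprintf("expansion exceeds the %d-world cap", max_worlds))
    }
  }
  dedup_worlds(out)
}

#' Enumerate the possible phenotypes a PL String denotes
#'
#' Expands an expression into the exact set of possible phenotype worlds.
#' Each world is a set of molecule labels; heterodimers are one molecule,
#' written `alpha~beta` (a heterodimer is distinct from the pair of its
#' subunits reported with `+`). With `subunits = TRUE` the must/may presence
#' sets are additionally computed over constituent chains, which answers
#' questions such as whether one alpha chain is shared by every alternative
#' heterodimer.
#'
#' @param expr A `pl_expr` or PL String.
#' @param options A [pl_options()] list (used if `expr` is text).
#' @param max_worlds Abort with `EXPANSION_TOO_LARGE` beyond this many worlds.
#' @param subunits Also compute must/may sets over constituent atoms.
#' @return A `pl_expansion`: list with `worlds` (list of sorted character
#'   vectors), `count`, `must_set`, `may_set` and, when requested,
#'   `must_subunits`/`may_subunits`.
#' @export
#' @examples
#' pl_expand("HLA-A*01:01/HLA-A*01:02+HLA-A*02:01")$count
#' pl_expand("A*01:01%A*01:02")$count
pl_expand <- function(expr, options = pl_options(), max_worlds = 1e6,
                      subunits = FALSE) {
  if (is.character(expr)) expr <- pl_parse(expr, options)
  check_expr_invariants(expr)
  worlds <- worlds_rec(expr, max_worlds)
  must <- Reduce(intersect, worlds)
  may <- sort(unique(unlist(worlds)), method = "radix")
  out <- list(
    worlds = worlds,
    count = length(worlds),
    must_set = sort(must, method = "radix"),
    may_set = may,
    expression = expr
  )
  if (subunits) {
    split_mols <- function(w) unique(unlist(strsplit(w, "~", fixed = TRUE)))
    sub_worlds <- lapply(worlds, split_mols)
    out$must_subunits <- sort(Reduce(intersect, sub_worlds), method = "radix")
    out$may_subunits <- sort(unique(unlist(sub_worlds)), method = "radix")
  }
  structure(out, class = "pl_expansion")
}

#' @export
print.pl_expansion <- function(x, ...) {
  cat("<pl_expansion> ", x$count, " possible phenotype world(s)\n", sep = "")
  show <- utils::head(x$worlds, 8L)
  for (w in show) cat("  {", paste(w, collapse = ", "), "}\n", sep = "")
  if (x$count > 8L) cat("  ...\n")
  cat("  must:", if (length(x$must_set)) paste(x$must_set, collapse = ", ") else "(none)", "\n")
  cat("  may: ", paste(x$may_set, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an expansion into a long molecule-by-world tibble
#'
#' @param x A `pl_expansion`.
#' @param ... Unused.
#' @return A tibble with columns `world` (index), `molecule`.
#' @method tidy pl_expansion
#' @export
tidy.pl_expansion <- function(x, ...) {
  tibble::tibble(
    world = rep(seq_along(x$worlds), lengths(x$worlds)),
    molecule = unlist(x$worlds) %||% character()
  )
}

#' One-row summary of an expansion
#'
#' @param x A `pl_expansion`.
#' @param ... Unused.
#' @return A tibble with `n_worlds`, `n_must`, `n_may`.
#' @method glance pl_expansion
#' @export
glance.pl_expansion <- function(x, ...) {
  tibble::tibble(n_worlds = x$count,
                 n_must = length(x$must_set),
                 n_may = length(x$may_set))
}

#' Plot which molecules occur in which possible worlds
#'
#' @param object A `pl_expansion`.
#' @param ... Unused.
#' @return A ggplot object: molecules against worlds, must-molecules filled
#'   differently from may-molecules.
#' @method autoplot pl_expansion
#' @export
autoplot.pl_expansion <- function(object, ...) {
  d <- tidy(object)
  d$presence <- ifelse(d$molecule %in% object$must_set, "must", "may")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$world), y = .data$molecule,
                                  fill = .data$presence)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::labs(x = "possible world", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Count possible phenotypes without full enumeration where possible
#'
#' Uses closed forms — products over `AND`, sums over `XOR`,
#' `prod(n_i + 1) - 1` over `IOR` — when no molecule is shared between
#' sibling branches (so no cross-branch world can collide), and falls back
#' to enumeration otherwise.
#'
#' @param expr A `pl_expr` or PL String.
#' @param options A [pl_options()] list.
#' @param max_worlds Enumeration cap for the fallback path.
#' @return An integer count, equal to `pl_expand(expr)$count`.
#' @export
#' @examples
#' pl_count("A*01:01/A*01:02/A*01:03")
pl_count <- function(expr, options = pl_options(), max_worlds = 1e6) {
  if (is.character(expr)) expr <- pl_parse(expr, options)
  check_expr_invariants(expr)
  mols <- function(e) {
    if (e$node_kind %in% c("ATOM", "HETERODIMER")) return(molecule_key(e))
    unique(unlist(lapply(e$children, mols)))
  }
  count_rec <- function(e) {
    if (e$node_kind %in% c("ATOM", "HETERODIMER")) return(1)
    branch_mols <- lapply(e$children, mols)
    shared <- FALSE
    if (length(branch_mols) > 1L) {
      all_m <- unlist(branch_mols)
      shared <- anyDuplicated(all_m) > 0L
    }
    if (shared) return(NA_real_)  # fall back to enumeration at top
    ns <- vapply(e$children, count_rec, numeric(1))
    if (anyNA(ns)) return(NA_real_)
    switch(e$node_kind,
           AND = prod(ns),
           XOR = sum(ns),
           IOR = prod(ns + 1) - 1)
  }
  n <- count_rec(expr)
  if (is.na(n)) n <- pl_expand(expr, max_worlds = max_worlds)$count
  as.integer(n)
}

#' Molecules present in every / any possible world
#'
#' `pl_must()` returns the molecules common to all worlds ("is present");
#' `pl_may()` the molecules appearing in at least one world ("may be
#' present").
#'
#' @param expr A `pl_expr` or PL String.
#' @param options A [pl_options()] list.
#' @param subunits Operate over constituent chains instead of whole
#'   molecules (a heterodimer contributes its alpha and beta atoms).
#' @return A sorted character vector of molecule labels.
#' @export
#' @examples
#' pl_must("A2+B7")
#' pl_may("A*02:01/A*02:02")
pl_must <- function(expr, options = pl_options(), subunits = FALSE) {
  x <- pl_expand(expr, options, subunits = subunits)
  if (subunits) x$must_subunits else x$must_set
}

#' @rdname pl_must
#' @export
pl_may <- function(expr, options = pl_options(), subunits = FALSE) {
  x <- pl_expand(expr, options, subunits = subunits)
  if (subunits) x$may_subunits else x$may_set
}

QUALIFIERS <- c("positive", "negative", "inconclusive")

#' Attach an assay-result qualifier to a composition
#'
#' A test result pairs an HLA composition with a `positive`, `negative` or
#' `inconclusive` qualifier describing the sample's reactivity against that
#' composition. The qualifier describes reactivity; it does not alter the
#' composition's expansion semantics.
#'
#' @param expr A `pl_expr` or PL String.
#' @param qualifier One of `"positive"`, `"negative"`, `"inconclusive"`.
#' @param options A [pl_options()] list.
#' @return A `pl_result`: list with `expression` and `qualifier`.
#' @export
#' @examples
#' pl_result(pl_parse("A2+B7"), "positive")
pl_result <- function(expr, qualifier, options = pl_options()) {
  if (is.character(expr)) expr <- pl_parse(expr, options)
  if (!is.character(qualifier) || length(qualifier) != 1L ||
      !qualifier %in% QUALIFIERS) {
    pl_abort("BAD_QUALIFIER",
             sprintf("qualifier must be one of %s",
                     paste(QUALIFIERS, collapse = ", ")))
  }
  structure(list(expression = expr, qualifier = qualifier), class = "pl_result")
}

#' @export
print.pl_result <- function(x, ...) {
  cat("<pl_result> ", pl_serialize(x$expression), " [", x$qualifier, "]\n",
      sep = "")
  invisible(x)
}
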