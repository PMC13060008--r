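# Independent possible-worlds oracle.
#
# Rather than composing world sets bottom-up (the package's algorithm), this
# oracle enumerates GLOBAL truth assignments: each XOR node is assigned one
# live branch, each IOR node a non-empty live subset, and the molecules on
# live paths are collected into one candidate world per assignment.
# Duplicate worlds across assignments are merged at the end.

oracle_molecule <- function(e) {
  if (e$node_kind == "ATOM") return(e$atom$normalized_text)
  paste(sort(vapply(e$children, function(c) c$atom$normalized_text,
                    character(1)), method = "radix"),
        collapse = "~")
}

oracle_worlds <- function(expr) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  specs <- list()
  annotate <- function(e) {
    if (e$node_kind %in% c("XOR", "IOR")) {
      counter$n <- counter$n + 1L
      k <- length(e$children)
      opts <- if (e$node_kind == "XOR") {
        lapply(seq_len(k), identity)
      } else {
        lapply(seq_len(2L^k - 1L), function(m) {
          which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
        })
      }
      specs[[counter$n]] <<- opts
      e$choice_id <- counter$n
    }
    if (e$node_kind != "ATOM") e$children <- lapply(e$children, annotate)
    e
  }
  expr <- annotate(expr)

  collect <- function(e, assignment) {
    if (e$node_kind %in% c("ATOM", "HETERODIMER")) return(oracle_molecule(e))
    live <- switch(e$node_kind,
      AND = seq_along(e$children),
      XOR = specs[[e$choice_id]][[assignment[e$choice_id]]],
      IOR = specs[[e$choice_id]][[assignment[e$choice_id]]]
    )
    unlist(lapply(e$children[live], collect, assignment = assignment))
  }

  if (length(specs) == 0L) {
    worlds <- list(sort(unique(collect(expr, integer())), method = "radix"))
  } else {
    grid <- expand.grid(lapply(specs, seq_along))
    worlds <- lapply(seq_len(nrow(grid)), function(r) {
      sort(unique(collect(expr, as.integer(grid[r, ]))), method = "radix")
    })
  }
  keys <- vapply(worlds, paste, character(1), collapse = "|")
  worlds[!duplicated(keys)]
}

worlds_setequal <- function(a, b) {
  ka <- sort(vapply(a, paste, character(1), collapse = "|"))
  kb <- sort(vapply(b, paste, character(1), collapse = "|"))
  identical(ka, kb)
}

# Permute the operands of every node (deterministically under the caller's
# RNG state) without changing semantics.
permute_expr <- function(e) {
  if (e$node_kind == "ATOM") return(e)
  e$children <- lapply(e$children, permute_expr)
  e$children <- e$children[sample.int(length(e$children))]
  e
}
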