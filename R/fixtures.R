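# Worked-example corpus and a seeded generator of random PL Strings.

expr_shape <- function(expr) {
  if (expr$node_kind == "ATOM") return("ATOM")
  if (expr$node_kind == "HETERODIMER") return("HET")
  paste0(expr$node_kind, "(",
         paste(vapply(expr$children, expr_shape, character(1)), collapse = ","),
         ")")
}

#' The worked-example PL String corpus
#'
#' The published worked examples of the grammar — one phenotyping-reagent
#' string and the antibody-interpretation strings — with hand-encoded
#' expectations: the tree shape each must parse to, its leaf-atom count,
#' the number of possible phenotype worlds it denotes, and the size of its
#' must-present molecule set.
#'
#' @return A tibble with columns `plstring`, `context`, `namespace`,
#'   `shape`, `n_atoms`, `n_worlds`, `n_must`.
#' @export
#' @examples
#' pl_corpus()
pl_corpus <- function() {
  tibble::tribble(
    ~plstring, ~context, ~namespace, ~shape, ~n_atoms, ~n_worlds, ~n_must,
    "HLA-A*01:01/HLA-A*01:02+HLA-A*02:01", "reagent", "who",
      "AND(XOR(ATOM,ATOM),ATOM)", 3L, 2L, 1L,
    "HLA-A*01:01%HLA-A*01:02+HLA-A*02:01", "result", "who",
      "AND(IOR(ATOM,ATOM),ATOM)", 3L, 3L, 1L,
    "A2+A68+A69+B57+B58", "result", "optn",
      "AND(ATOM,ATOM,ATOM,ATOM,ATOM)", 5L, 1L, 5L,
    "HLA-A*01:02+HLA-A*02:01+HLA-B*07:02", "result", "who",
      "AND(ATOM,ATOM,ATOM)", 3L, 1L, 3L,
    "HLA-DQA1*05:01~HLA-DQB1*02:01%HLA-DPA1*01:03~HLA-DPB1*04:02", "result", "who",
      "IOR(HET,HET)", 4L, 3L, 0L,
    "HLA-DPA1*01:04~HLA-DPB1*02:01%HLA-DPA1*01:04~HLA-DPB1*04:02", "result", "who",
      "IOR(HET,HET)", 4L, 3L, 0L,
    paste0("HLA-DPA1*01:04~HLA-DPB1*04:02%HLA-DPA1*02:01~HLA-DPB1*04:02",
           "%HLA-DPA1*01:03~HLA-DPB1*04:02"), "result", "who",
      "IOR(HET,HET,HET)", 6L, 7L, 0L,
    "HLA-DPA1*01:04+HLA-DPB1*04:01", "result", "who",
      "AND(ATOM,ATOM)", 2L, 1L, 2L,
    "HLA-DQA1*05:01~HLA-DQB1*02:01+HLA-DPA1*01:03~HLA-DPB1*04:02", "result", "who",
      "AND(HET,HET)", 4L, 1L, 2L,
    "HLA-DQA1*05:01~HLA-DQB1*02:01/HLA-DPA1*01:03~HLA-DPB1*04:02", "result", "who",
      "XOR(HET,HET)", 4L, 2L, 0L,
    "HLA-DPA1*01:04~HLA-DPB1*04:02/HLA-DPA1*01:03~HLA-DPB1*04:02", "result", "who",
      "XOR(HET,HET)", 4L, 2L, 0L
  )
}

#' Generator settings for random PL Strings
#'
#' @param max_depth Maximum nesting depth of operator nodes.
#' @param max_fanout Maximum operands per AND/XOR/IOR node.
#' @param p_leaf Probability that a position below the root is a leaf.
#' @param p_heterodimer Probability that a leaf is an alpha~beta heterodimer
#'   (drawn from the vocabulary's pairing rules).
#' @param p_inject Probability that a generated string is corrupted with a
#'   GL String-only delimiter or a dangling operator, for negative tests.
#' @return A list of class `pl_generator_spec`.
#' @export
pl_generator_spec <- function(max_depth = 3L, max_fanout = 3L, p_leaf = 0.4,
                              p_heterodimer = 0.25, p_inject = 0) {
  structure(list(max_depth = as.integer(max_depth),
                 max_fanout = as.integer(max_fanout),
                 p_leaf = p_leaf, p_heterodimer = p_heterodimer,
                 p_inject = p_inject),
            class = "pl_generator_spec")
}

vocab_pairings <- function(vocab) {
  e <- vocab$entries
  alphas <- e[e$chain_role == "ALPHA", ]
  betas <- e[e$chain_role == "BETA", ]
  if (nrow(alphas) == 0 || nrow(betas) == 0) return(NULL)
  pairs <- list()
  for (i in seq_len(nrow(alphas))) {
    ok <- betas$locus %in% alphas$partner_loci[[i]] &
      vapply(betas$partner_loci, function(p) alphas$locus[i] %in% p, logical(1))
    for (j in which(ok)) {
      pairs[[length(pairs) + 1L]] <- c(alphas$atom[i], betas$atom[j])
    }
  }
  if (length(pairs) == 0) NULL else pairs
}

# Without a grouping construct, a node's operands may only use strictly
# tighter-binding delimiters, so trees are generated down the binding
# hierarchy AND > IOR > XOR > (heterodimer | atom).
gen_expr <- function(spec, atoms, pairs, depth, allowed = c("AND", "IOR", "XOR")) {
  leaf <- depth >= spec$max_depth || length(allowed) == 0L ||
    (depth > 0L && stats::runif(1) < spec$p_leaf)
  if (leaf) {
    if (!is.null(pairs) && stats::runif(1) < spec$p_heterodimer) {
      p <- pairs[[sample.int(length(pairs), 1L)]]
      return(new_expr("HETERODIMER", children = lapply(p, function(t) {
        new_expr("ATOM", atom = pl_atom(t))
      })))
    }
    return(new_expr("ATOM", atom = pl_atom(atoms[sample.int(length(atoms), 1L)])))
  }
  kind <- allowed[sample.int(length(allowed), 1L)]
  tighter <- switch(kind, AND = c("IOR", "XOR"), IOR = "XOR", XOR = character())
  k <- sample(2:spec$max_fanout, 1L)
  children <- lapply(seq_len(k), function(i) {
    gen_expr(spec, atoms, pairs, depth + 1L, allowed = tighter)
  })
  new_expr(kind, children = children)
}

corrupt_string <- function(text) {
  mode <- sample.int(3L, 1L)
  if (mode == 1L) {
    gl <- c("^", "|", "?")[sample.int(3L, 1L)]
    paste0(text, gl, "X1")        # GL_ONLY_DELIMITER
  } else if (mode == 2L) {
    paste0(text, "+")             # trailing DANGLING_OPERATOR
  } else {
    paste0("+", text)             # leading DANGLING_OPERATOR
  }
}

#' Generate random PL Strings from a vocabulary
#'
#' Draws well-formed expression trees (in parser normal form: associative
#' chains already flattened, heterodimer leaves using valid alpha/beta
#' pairings) and serializes them. Output is fully determined by
#' `(spec, seed)`. With `p_inject > 0`, the stated fraction of strings is
#' corrupted so that they fail tokenization, for negative testing.
#'
#' @param n Number of strings.
#' @param vocab A `pl_vocabulary` supplying the atoms.
#' @param spec A [pl_generator_spec()].
#' @param seed Integer seed; the generator never perturbs the session RNG.
#' @param as_expressions Return the `pl_expr` trees instead of text (only
#'   meaningful with `p_inject = 0`).
#' @return A character vector of PL Strings, or a list of `pl_expr`.
#' @export
#' @examples
#' pl_generate(3, pl_example_vocabulary("who"), seed = 1)
pl_generate <- function(n, vocab, spec = pl_generator_spec(), seed = 1L,
                        as_expressions = FALSE) {
  stopifnot(n >= 1L)
  atoms <- vocab$entries$atom[vocab$entries$class != "MAC"]
  if (length(atoms) == 0L) {
    pl_abort("SPEC_UNSATISFIABLE", "vocabulary supplies no atoms")
  }
  pairs <- vocab_pairings(vocab)
  if (spec$p_heterodimer > 0 && is.null(pairs) && spec$p_heterodimer >= 1) {
    pl_abort("SPEC_UNSATISFIABLE",
             "heterodimer leaves requested but the vocabulary has no alpha/beta pairs")
  }
  withr::with_seed(seed, {
    exprs <- lapply(seq_len(n), function(i) {
      gen_expr(spec, atoms, pairs, depth = 0L)
    })
    if (as_expressions) {
      exprs
    } else {
      texts <- vapply(exprs, pl_serialize, character(1))
      if (spec$p_inject > 0) {
        hit <- stats::runif(n) < spec$p_inject
        texts[hit] <- vapply(texts[hit], corrupt_string, character(1))
      }
      texts
    }
  })
}
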