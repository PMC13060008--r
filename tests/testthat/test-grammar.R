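test_that("tokenizer splits atoms and delimiters, stripping whitespace", {
  toks <- pl_tokenize("A2+B7")
  expect_equal(toks$kind, c("ATOM_TEXT", "OP_PLUS", "ATOM_TEXT"))
  expect_equal(toks$text, c("A2", "+", "B7"))
  expect_equal(toks$start, c(0L, 2L, 3L))

  toks <- pl_tokenize("DPA1*01:03 ~ DPB1*06:01")
  expect_equal(toks$text, c("DPA1*01:03", "~", "DPB1*06:01"))
  expect_equal(attr(toks, "normalized"), "DPA1*01:03~DPB1*06:01")

  toks <- pl_tokenize("B7")
  expect_equal(nrow(toks), 1L)
  expect_equal(toks$kind, "ATOM_TEXT")

  # offsets tile the normalized input
  toks <- pl_tokenize("HLA-A*01:01/HLA-A*01:02+HLA-A*02:01")
  expect_equal(toks$start, c(0L, cumsum(nchar(toks$text)))[seq_len(nrow(toks))])
  expect_true(all(toks$text[toks$kind != "ATOM_TEXT"] %in% c("+", "/", "~", "%")))
})

test_that("tokenizer rejects bad inputs with distinct codes", {
  expect_pl_error(pl_tokenize(""), "EMPTY_INPUT")
  expect_pl_error(pl_tokenize("   "), "EMPTY_INPUT")
  expect_pl_error(pl_tokenize("A*01:01^B*07:02"), "GL_ONLY_DELIMITER")
  expect_pl_error(pl_tokenize("A*01:01|B*07:02"), "GL_ONLY_DELIMITER")
  expect_pl_error(pl_tokenize("A*01:01?"), "GL_ONLY_DELIMITER")
  expect_pl_error(pl_tokenize("A2++B7"), "DANGLING_OPERATOR")
  expect_pl_error(pl_tokenize("+A2"), "DANGLING_OPERATOR")
  expect_pl_error(pl_tokenize("A2+"), "DANGLING_OPERATOR")
  expect_pl_error(pl_tokenize("+"), "DANGLING_OPERATOR")
  expect_pl_error(pl_tokenize("who#3.58.0#A2"), "PLSC_IN_PLSTRING")
  expect_pl_error(pl_tokenize("HLA A2+B7"), "ATOM_WHITESPACE")
})

test_that("unicode hyphens normalize and '-' stays atom-internal", {
  # typeset input with U+2010 in the prefix
  toks <- pl_tokenize("HLA‐A*01:01+HLA‐B*07:02")
  expect_equal(toks$text[1], "HLA-A*01:01")
  a <- pl_parse("DP-0402")
  expect_equal(a$atom$normalized_text, "DP-0402")
  expect_true(pl_parse("A-0265")$atom$proposed)
})

test_that("atoms record prefix and expression suffix", {
  a <- pl_atom("HLA-B*07:02")
  expect_true(a$prefix_present)
  expect_equal(a$normalized_text, "B*07:02")
  b <- pl_atom("A*24:09N")
  expect_equal(b$expression_suffix, "N")
  expect_true(is.na(pl_atom("A*24:09")$expression_suffix))
  expect_true(is.na(pl_atom("A24")$expression_suffix))
})

test_that("parser builds the worked-example tree shapes", {
  e <- pl_parse("HLA-A*01:01/HLA-A*01:02+HLA-A*02:01")
  expect_equal(e$node_kind, "AND")
  expect_equal(e$children[[1]]$node_kind, "XOR")
  expect_equal(e$children[[2]]$node_kind, "ATOM")
  expect_equal(e$children[[2]]$atom$normalized_text, "A*02:01")

  e <- pl_parse("HLA-DQA1*05:01~HLA-DQB1*02:01%HLA-DPA1*01:03~HLA-DPB1*04:02")
  expect_equal(e$node_kind, "IOR")
  expect_equal(vapply(e$children, function(c) c$node_kind, character(1)),
               c("HETERODIMER", "HETERODIMER"))

  e <- pl_parse("A2")
  expect_equal(e$node_kind, "ATOM")
})

test_that("associative chains flatten to one n-ary node", {
  e <- pl_parse("A2+A68+A69+B57+B58")
  expect_equal(e$node_kind, "AND")
  expect_length(e$children, 5L)
  expect_true(all(vapply(e$children, function(c) c$node_kind, character(1)) == "ATOM"))

  e <- pl_parse("A*02:01/A*02:02/A*02:03")
  expect_equal(e$node_kind, "XOR")
  expect_length(e$children, 3L)
})

test_that("tilde chains beyond two atoms are an arity error", {
  expect_pl_error(pl_parse("DPA1*01:03~DPB1*06:01~DPB1*04:02"), "HETERODIMER_ARITY")
  expect_pl_error(pl_parse("A2~B7~DR2~DQ2"), "HETERODIMER_ARITY")
  e <- pl_parse("DPA1*01:03~DPB1*06:01")
  expect_equal(e$node_kind, "HETERODIMER")
  expect_length(e$children, 2L)
})

test_that("strict percent context escalates the protein-context warning", {
  expect_pl_error(
    pl_parse("A*01:01%A*01:02", pl_options(strict_percent_context = TRUE)),
    "PERCENT_CONTEXT"
  )
  # permissive default parses, and validation carries a WARNING issue
  e <- pl_parse("A*01:01%A*01:02")
  expect_equal(e$node_kind, "IOR")
  rep <- pl_validate(e, pl_example_vocabulary("who"))
  expect_true(rep$valid)
  expect_true("PERCENT_CONTEXT" %in% rep$issues$code)
  expect_equal(rep$issues$severity[rep$issues$code == "PERCENT_CONTEXT"], "WARNING")
  # antigen-level % raises no such issue
  rep2 <- pl_validate("A2402%A2403", who_vocab)
  expect_false("PERCENT_CONTEXT" %in% rep2$issues$code)
})

test_that("serialization round-trips and canonical form is order-invariant", {
  s <- "A2+A68+A69+B57+B58"
  expect_identical(pl_serialize(pl_parse(s)), s)

  expect_identical(pl_serialize(pl_parse("B7+A2"), canonical = TRUE),
                   pl_serialize(pl_parse("A2+B7"), canonical = TRUE))
  expect_identical(pl_serialize(pl_parse("B7+A2"), canonical = TRUE), "A2+B7")

  # heterodimer subunit order is free; canonical puts the alpha chain first
  # once chain roles are known, lexicographic order otherwise
  e1 <- pl_parse("DPB1*02:02~DPA1*01:04")
  e2 <- pl_parse("DPA1*01:04~DPB1*02:02")
  expect_identical(pl_serialize(e1, canonical = TRUE),
                   pl_serialize(e2, canonical = TRUE))
  expect_identical(pl_serialize(e1, canonical = TRUE), "DPA1*01:04~DPB1*02:02")

  # canonicalization is idempotent
  c1 <- pl_serialize(pl_parse("B*07:02/A*02:01%A24"), canonical = TRUE)
  expect_identical(pl_serialize(pl_parse(c1), canonical = TRUE), c1)
})

test_that("operator table reproduces the published precedence metadata", {
  ops <- pl_operators()
  expect_equal(nrow(ops), 4L)
  expect_setequal(ops$symbol, c("+", "~", "%", "/"))
  expect_equal(ops$published_precedence[ops$symbol == "+"], 1L)
  expect_equal(ops$published_precedence[ops$symbol == "~"], 2L)
  expect_equal(ops$published_precedence[ops$symbol == "%"], 3L)
  expect_equal(ops$published_precedence[ops$symbol == "/"], 4L)
  expect_equal(ops$operation[ops$symbol == "%"], "Inclusive OR")
  # parser binding: tilde tightest, plus loosest
  expect_equal(ops$binding_rank[order(ops$binding_rank)][1], 1L)
  expect_equal(ops$symbol[ops$binding_rank == 1L], "~")
  expect_equal(ops$symbol[ops$binding_rank == 4L], "+")
})

test_that("GL delimiter lint reports GL-only symbols and shared slash", {
  rep <- pl_lint_gl("A*01:01+B*07:02|B*08:01")
  gl <- rep$issues[rep$issues$code == "GL_ONLY_DELIMITER", ]
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$position, 15L)

  rep <- pl_lint_gl("A?B^C")
  expect_equal(sum(rep$issues$code == "GL_ONLY_DELIMITER"), 2L)

  rep <- pl_lint_gl("A2+B7")
  expect_equal(nrow(rep$issues), 0L)
  expect_true(rep$valid)

  rep <- pl_lint_gl("A*02:01/A*02:02")
  expect_equal(rep$issues$code, "SHARED_GL_DELIMITER")
  expect_true(rep$valid)

  tab <- pl_gl_delimiters()
  expect_equal(sum(tab$gl), 6L)
  expect_equal(sum(tab$pl), 4L)
  expect_setequal(tab$symbol[tab$gl & !tab$pl], c("^", "|", "?"))
  expect_equal(tab$symbol[tab$pl & !tab$gl], "%")
})

test_that("fuzz: generated strings round-trip and heterodimers stay binary", {
  exprs <- pl_generate(300, who_vocab, pl_generator_spec(max_depth = 3),
                       seed = 11, as_expressions = TRUE)
  for (e in exprs) {
    s <- pl_serialize(e)
    back <- pl_parse(s)
    expect_true(pl_expr_equal(back, e))
    # canonical serialization is idempotent and order-invariant
    can <- pl_serialize(e, canonical = TRUE)
    expect_identical(pl_serialize(pl_parse(can), canonical = TRUE), can)
    check_het <- function(x) {
      if (x$node_kind == "HETERODIMER") {
        expect_length(x$children, 2L)
        expect_true(all(vapply(x$children, function(c) c$node_kind, character(1)) == "ATOM"))
      }
      if (x$node_kind != "ATOM") lapply(x$children, check_het)
      invisible(NULL)
    }
    check_het(back)
  }
})
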