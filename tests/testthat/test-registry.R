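test_that("built-in registry holds exactly the four governed namespaces", {
  ns <- pl_namespaces()
  expect_setequal(ns$id[ns$builtin], c("et", "nmdp", "optn", "who"))
  expect_equal(nrow(ns[ns$builtin, ]), 4L)
})

test_that("extension registration requires all four attestations", {
  on.exit(pl_reset_namespaces(), add = TRUE)
  expect_pl_error(
    pl_register_namespace("lab1", "Example Lab", governance = TRUE,
                          transparency = TRUE, compatibility = TRUE),
    "ATTESTATION_MISSING"
  )
  pl_register_namespace("lab1", "Example Lab", governance = TRUE,
                        transparency = TRUE, compatibility = TRUE,
                        version_control = TRUE)
  expect_true("lab1" %in% pl_namespaces()$id)
})

test_that("vocabulary loader enforces the TSV dialect", {
  expect_equal(who_vocab$namespace_id, "who")
  expect_equal(who_vocab$version_token, "3.58.0")
  expect_true(all(c("B*07:02", "Bw4", "A2403") %in% who_vocab$entries$atom))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), tmp)
  expect_pl_error(pl_load_vocabulary(tmp), "BAD_HEADER")

  writeLines(c("#namespace=who version=3.58.0",
               "atom\tclass\tlocus\tchain_role\tpartner_loci",
               "A2\tANTIGEN\tA\t\t",
               "A2\tANTIGEN\tA\t\t"), tmp)
  expect_pl_error(pl_load_vocabulary(tmp), "DUPLICATE_ATOM")

  writeLines(c("#namespace=who version=v3",
               "atom\tclass\tlocus\tchain_role\tpartner_loci"), tmp)
  expect_pl_error(pl_load_vocabulary(tmp), "BAD_VERSION_TOKEN")
})

test_that("classification is prefix- and suffix-invariant", {
  a <- pl_classify("HLA-B*07:02", who_vocab)
  b <- pl_classify("B*07:02", who_vocab)
  expect_equal(a$atom_class, "PROTEIN")
  expect_equal(a$atom_class, b$atom_class)
  expect_equal(a$locus, b$locus)

  # expression-suffixed entry resolves from its bare spelling and vice versa
  expect_equal(pl_classify("A*24:09", who_vocab)$atom_class, "PROTEIN")
  expect_equal(pl_classify("A*24:09N", who_vocab)$atom_class, "PROTEIN")

  expect_equal(pl_classify("Bw4", who_vocab)$atom_class, "EPITOPE")
  assoc <- pl_classify("A-0265", who_vocab)
  expect_equal(assoc$atom_class, "ASSOCIATED_ANTIGEN")
  expect_true(assoc$proposed)

  expect_pl_error(pl_classify("ZZ9", who_vocab), "UNKNOWN_ATOM")

  # prefix invariance over every WHO protein entry
  prots <- who_vocab$entries$atom[who_vocab$entries$class == "PROTEIN"]
  for (p in prots) {
    expect_equal(pl_classify(paste0("HLA-", p), who_vocab)$atom_class,
                 pl_classify(p, who_vocab)$atom_class)
  }
})

test_that("MAC expansion yields an XOR over the coded proteins", {
  x <- pl_expand_mac("A*02:AB", mac_table)
  expect_equal(x$node_kind, "XOR")
  expect_equal(pl_serialize(x), "A*02:01/A*02:02")

  expect_pl_error(pl_expand_mac("A*02:01", mac_table), "NOT_A_MAC")
  expect_pl_error(pl_expand_mac("A*02:ZZ", mac_table), "UNKNOWN_MAC")

  # expansion size equals the table entry length, via world enumeration
  for (i in seq_len(nrow(mac_table$codes))) {
    code <- mac_table$codes$code[i]
    x <- pl_expand_mac(paste0("A*02:", code), mac_table)
    expect_equal(pl_expand(x)$count, length(mac_table$codes$expansion[[i]]))
  }

  # expand -> serialize -> parse is a fixed point
  s <- pl_serialize(pl_expand_mac("A*02:ABC", mac_table))
  expect_identical(pl_serialize(pl_parse(s)), s)

  # full designations in the expansion are used verbatim
  expect_equal(pl_serialize(pl_expand_mac("A*02:GK", mac_table)),
               "A*02:01/A*02:05")
})

test_that("heterodimer pairing accepts alpha/beta in either order", {
  expect_true(pl_check_heterodimer("DQA1*05:01", "DQB1*02:01", who_vocab)$valid)
  expect_true(pl_check_heterodimer("DPB1*02:02", "DPA1*01:04", who_vocab)$valid)

  rep <- pl_check_heterodimer("A*02:01", "B*07:02", who_vocab)
  expect_false(rep$valid)
  expect_true("NOT_HETERODIMERIC" %in% rep$issues$code)

  rep <- pl_check_heterodimer("DQA1*05:01", "DPB1*04:02", who_vocab)
  expect_true("LOCUS_MISMATCH" %in% rep$issues$code)

  rep <- pl_check_heterodimer("DPA1*01:03", "DPA1*01:04", who_vocab)
  expect_true("SAME_CHAIN" %in% rep$issues$code)

  # antigen-level pairing from the ET example vocabulary
  expect_true(pl_check_heterodimer("SDQA05", "DQ2", et_vocab)$valid)

  # symmetry over every fixture atom pair
  atoms <- who_vocab$entries$atom
  pairs <- expand.grid(a = atoms, b = atoms, stringsAsFactors = FALSE)
  pairs <- pairs[withr::with_seed(1L, sample.int(nrow(pairs), 80L)), ]
  for (k in seq_len(nrow(pairs))) {
    expect_equal(
      pl_check_heterodimer(pairs$a[k], pairs$b[k], who_vocab)$valid,
      pl_check_heterodimer(pairs$b[k], pairs$a[k], who_vocab)$valid
    )
  }
})

test_that("expression validation aggregates checks over the whole tree", {
  rep <- pl_validate("A2+A68+A69+B57+B58", optn_vocab)
  expect_true(rep$valid)
  e <- pl_parse("A2+A68+A69+B57+B58")
  cls <- vapply(e$children, function(c) pl_classify(c$atom, optn_vocab)$atom_class,
                character(1))
  expect_true(all(cls == "ANTIGEN"))

  # atoms foreign to the namespace are flagged (no cross-namespace mixing)
  rep <- pl_validate("A2+A*02:AB", optn_vocab)
  expect_false(rep$valid)
  expect_true("UNKNOWN_ATOM" %in% rep$issues$code)

  rep <- pl_validate("B*07:02", who_vocab)
  expect_true(rep$valid)
  expect_equal(nrow(rep$issues), 0L)

  rep <- pl_validate("DQA1*05:01~DQB1*02:01+A*02:01", who_vocab)
  expect_true(rep$valid)

  rep <- pl_validate("DQA1*05:01~DPB1*04:02", who_vocab)
  expect_false(rep$valid)

  # duplicate operands warn but stay valid
  rep <- pl_validate("A2%A2", optn_vocab)
  expect_true(rep$valid)
  expect_true("DUPLICATE_OPERAND" %in% rep$issues$code)
})
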