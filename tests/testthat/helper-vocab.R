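# Shared fixtures: bundled example vocabularies and MAC table.
who_vocab <- pl_example_vocabulary("who")
optn_vocab <- pl_example_vocabulary("optn")
et_vocab <- pl_example_vocabulary("et")
nmdp_vocab <- pl_example_vocabulary("nmdp")
mac_table <- pl_example_mac_table()

expect_pl_error <- function(expr, code) {
  cnd <- tryCatch(expr, plstring_error = function(c) c)
  expect_s3_class(cnd, "plstring_error")
  expect_identical(pl_error_code(cnd), code)
  invisible(cnd)
}
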