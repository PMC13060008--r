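# plstring

Parse, validate and exchange HLA **phenotype list (PL) Strings** — the
grammar used to report antigen- and protein-level HLA data from antibody
assays (single antigen bead panels, crossmatches) and from their clinical
interpretation (present / acceptable / unacceptable specificities).

Histocompatibility reports describe HLA *phenotypes*: which proteins or
antigens a reagent carries, which specificities a serum reacted with, and
which antigens a transplant candidate must avoid. Unlike genotype list (GL)
Strings, these lists cannot carry locus or phase information, but they must
express *ambiguity* ("one of these proteins") and *heterodimers* (class II
alpha~beta pairs). The PL String grammar does this with four delimiters:

| delimiter | operation | meaning |
|---|---|---|
| `+` | AND | all operands are present (`A2+B7`) |
| `~` | heterodimer | one alpha and one beta chain form one molecule (`DPA1*01:03~DPB1*06:01`) |
| `%` | inclusive OR | either or both operands present (`A2402%A2403`) |
| `/` | exclusive OR | exactly one operand present (`A*02:01/A*02:02`) |

`~` binds tightest, then `/`, then `%`, then `+`; operand order is never
significant. The GL String-only delimiters `^`, `|`, `?` are rejected with
structured errors. A PL String becomes a **PL String Code (PLSC)** by
prefixing the governing namespace (`who`, `optn`, `et`, `nmdp`) and a
vocabulary release or event date: `who#3.58.0#HLA-A*02:01+HLA-B*07:02`.
PLSCs travel inside HL7 FHIR `valueCodeableConcept` JSON and HAML-style XML
report fragments.

The package provides:

* `pl_parse()`, `pl_tokenize()`, `pl_serialize()`, `pl_lint_gl()` — the
  grammar, with canonical serialization and structured error codes;
* `pl_load_vocabulary()`, `pl_classify()`, `pl_check_heterodimer()`,
  `pl_expand_mac()`, `pl_validate()` — namespace vocabularies, alpha/beta
  pairing rules and NMDP multiple allele code (MAC) expansion;
* `pl_expand()`, `pl_count()`, `pl_must()`, `pl_may()` — exact
  possible-phenotype ("worlds") semantics;
* `pl_encode()`, `pl_decode()`, `pl_split_by_event_date()` — the PLSC codec;
* `pl_to_fhir()` / `pl_from_fhir()`, `pl_to_haml()` / `pl_from_haml()`,
  `pl_convert()` — carrier embedding and conversion;
* `pl_generate()`, `pl_corpus()` — a seeded expression generator and the
  worked-example corpus;
* a command-line interface: `pl_cli()` and the wrapper script
  `inst/cli/plstring.R`.

Results are tibbles or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

An antibody result with exclusive protein ambiguity:

```r
library(plstring)

x <- pl_expand("HLA-A*01:01/HLA-A*01:02+HLA-A*02:01")
x
#> <pl_expansion> 2 possible phenotype world(s)
#>   {A*01:01, A*02:01}
#>   {A*01:02, A*02:01}
#>   must: A*02:01
#>   may:  A*01:01, A*01:02, A*02:01
```

`A*02:01` is present in every world; exactly one of `A*01:01` / `A*01:02`
accompanies it. With the inclusive `%` instead of `/`, the same list denotes
3 worlds (`either or both`). Heterodimer alternatives sharing a subunit:

```r
s <- "HLA-DPA1*01:04~HLA-DPB1*02:01%HLA-DPA1*01:04~HLA-DPB1*04:02"
pl_must(s)                   # no whole molecule is certain
#> character(0)
pl_must(s, subunits = TRUE)  # but the alpha chain is always present
#> [1] "DPA1*01:04"
```

Validation and exchange:

```r
vocab <- pl_example_vocabulary("optn")
pl_validate("A2+A68+A69+B57+B58", vocab)$valid
#> [1] TRUE

plsc <- pl_encode("optn", "2025-01-15", "A2+A68+A69+B57+B58", vocab)
plsc
#> [1] "optn#2025-01-15#A2+A68+A69+B57+B58"

cat(pl_to_haml(pl_diagnostic_report(plsc, type = "Unacceptable")))
#> <diagnostic-report>
#>   <specificities>
#>     <specificities-type>Unacceptable</specificities-type>
#>     <specificities-string>optn#2025-01-15#A2+A68+A69+B57+B58</specificities-string>
#>   </specificities>
#> </diagnostic-report>
```

The bundled vocabularies under `inst/extdata/` are small illustrative
examples; authoritative tables are maintained by each namespace's governing
body and load through `pl_load_vocabulary()` in the same TSV dialect.

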