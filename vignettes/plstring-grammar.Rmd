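---
title: "The PL String grammar: parsing, semantics and exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PL String grammar: parsing, semantics and exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plstring)
```

## The problem

HLA antibody assays and their clinical interpretation are reported at the
*phenotype* level: which proteins or antigens sit on a reagent bead, which
specificities a serum reacted against, which antigens are unacceptable for
a transplant candidate. These lists need two things a flat antigen list
cannot express: **ambiguity** (a bead known to carry one of two closely
related proteins; a serologic reactivity that either of two antigens could
explain) and **heterodimer identity** (a class II DQ or DP molecule is one
alpha chain plus one beta chain, and antibodies can be specific to the pair
rather than to either chain). The PL String grammar encodes both with four
delimiters over namespace-governed atoms; this package implements the
grammar, its possible-phenotype semantics, the PLSC provenance wrapper and
the JSON/XML carrier fragments.

## The grammar and its binding order

Atoms (protein names like `DQB1*02:01`, antigens like `A24`, associated
antigens like `A2403`, MAC codes like `A*02:AB`, match determinants and
epitopes like `Bw4`) are combined with:

* `+` — AND: all operands present;
* `~` — heterodimer: exactly two operands, one alpha and one beta chain,
  forming a single molecule;
* `%` — inclusive OR: either or both present;
* `/` — exclusive OR: exactly one present.

There is no grouping construct, so the relative binding tightness of the
delimiters fully determines every parse. The delimiter table of the
published grammar lists precedence integers (`+`=1, `~`=2, `%`=3, `/`=4) to
be evaluated in increasing order, but the accompanying worked examples are
only consistent with `~` binding *tightest*: a string such as
`DQA1*05:01~DQB1*02:01%DPA1*01:03~DPB1*04:02` is read everywhere as a
choice between two heterodimers, and `~` operands must be single chain
atoms. This package therefore parses with binding order (tightest to
loosest) `~`, `/`, `%`, `+` — the unique order that reproduces every worked
example — and preserves the table's printed integers as reporting metadata
in `pl_operators()$published_precedence`. The relative order of `/` versus `%`
follows the printed table; no worked example mixes them, so nothing else
constrains it.

```{r}
pl_operators()
```

Chains of one associative delimiter flatten to a single n-ary node
(`A2+A68+A69+B57+B58` is one AND with five children); a `~` chain of three
or more atoms is an arity error, because a heterodimer has exactly two
constituents. Operand order is never semantically significant
(`DPB1*02:02~DPA1*01:04` and `DPA1*01:04~DPB1*02:02` name the same
molecule); `pl_serialize(canonical = TRUE)` picks one representative per
equivalence class, placing the alpha chain first when chain roles are
known and sorting lexicographically otherwise.

Three further delimiters — `^`, `|`, `?` — belong to the genotype list (GL)
String grammar only and are rejected with a dedicated error code;
`pl_lint_gl()` reports them without failing, for triaging mixed input.

### Tolerances on real-world text

Reports copy-pasted from typeset documents carry Unicode hyphens (U+2010,
U+2011, U+2212) in `HLA-` prefixes and stray spaces around delimiters. By
default both are normalized away; whitespace *inside* an atom remains an
error, and `-` is always atom-internal (proposed associated antigens such
as `A-0265` and ET-style names such as `DP-0402` survive intact). Atom text
is matched case-sensitively: vocabulary names are case-significant.

### The `%` context question

The delimiter table restricts `%` to antigens, yet the worked examples
apply it between proteins and between heterodimers. We treat the worked
usage as normative: by default `%` between protein-level operands yields a
WARNING-severity issue in the validation report, and
`pl_options(strict_percent_context = TRUE)` upgrades it to an error for
pipelines that want the letter of the table.

## Namespaces and vocabularies

Which atoms are permissible is governed by the namespace authority — WHO
(protein, antigen and associated-antigen levels), OPTN, ET and NMDP — not
by this package. The four built-ins are fixed; extensions register only
with all four authority attestations (governance, transparency,
compatibility, version control). Vocabularies load from a deliberately
plain TSV dialect (one `#namespace=<id> version=<token>` line, a five-column
header, `|`-separated partner loci) so any authority table can be diffed
and supplied by the user. The bundled files under `inst/extdata/` are small
*examples* covering the atoms used in the worked examples and tests — a few
dozen atoms per namespace — and are not authoritative.

Classification is spelling-tolerant where the grammar says both spellings
are allowed: `HLA-B*07:02`/`B*07:02` resolve to one entry, as do
`A*24:09`/`A*24:09N` (expression-variant suffixes A, C, L, N, S, Q). The
comparison default is suffix-preserving; lookup aliases the two spellings
to one vocabulary entry rather than conflating them textually.

Heterodimer pairing rules ship as data in the same files (chain role plus
partner loci: DQA1↔DQB1, DPA1↔DPB1, DRA↔DRB1/3/4/5, and the antigen-level
`SDQA05`↔`DQ2` style in the ET example), because which pairings an
authority recognises is the authority's decision. `pl_check_heterodimer()`
is order-free and distinguishes `SAME_CHAIN`, `LOCUS_MISMATCH` and
`NOT_HETERODIMERIC` failures.

MAC codes expand through a separate user-suppliable table to an exclusive
OR over proteins — `A*02:AB` to `A*02:01/A*02:02` — since a MAC names
exactly one of its member alleles.

## Possible-phenotype semantics

A PL String denotes a set of possible phenotype *worlds*, each a set of
molecules:

* an atom or heterodimer denotes one world holding that one molecule — a
  heterodimer is a single molecule, deliberately distinct from the two
  separate chains reported as `DPA1*01:04+DPB1*04:01`;
* `AND` takes all unions of one world per operand;
* `XOR` realises exactly one operand;
* `IOR` realises any non-empty subset of operands.

Worlds are sets and the world list is deduplicated, so degenerate inputs
like `A2%A2` collapse (with a duplicate-operand warning in validation).
`pl_must()` intersects the worlds, `pl_may()` unions them. The heterodimer
examples narrate a subtlety: in
`DPA1*01:04~DPB1*02:01%DPA1*01:04~DPB1*04:02` no whole molecule is present
in every world, yet the alpha chain is. Molecule-level and subunit-level
queries are therefore separate (`subunits = TRUE` re-runs must/may over
constituent chains):

```{r}
s <- "HLA-DPA1*01:04~HLA-DPB1*02:01%HLA-DPA1*01:04~HLA-DPB1*04:02"
pl_expand(s)
pl_must(s, subunits = TRUE)
```

`pl_count()` uses closed forms (products over AND, sums over XOR,
`prod(n+1)-1` over IOR) whenever sibling branches share no molecule, and
falls back to enumeration otherwise; enumeration aborts beyond a
configurable cap (default 10^6 worlds) rather than exhausting memory.
Result qualifiers (`positive`, `negative`, `inconclusive`) annotate a
composition without altering its expansion — whether a negative result
should *exclude* worlds is an interpretation question the data format does
not decide, so the package only records the qualifier.

## PLSCs and carriers

`pl_encode()`/`pl_decode()` implement the `namespace#version#plstring`
code. The published description specifies `#` delimiting but not field
order; we mirror the GL String Code layout it extends (namespace first),
and the decoder additionally accepts the reversed legacy order with a
warning when the first segment visibly contains a PL String delimiter.
Version tokens are either a three-integer release (IPD-IMGT/HLA style) or
an ISO-8601 date — the mandated fallback when no release applies, dated by
reagent creation, result production or interpretation (a constraint on
*which* date that is cannot be machine-checked and is documented instead).
Mixing atoms from different namespaces in one string is rejected; records
spanning several event dates split into one PLSC per date
(`pl_split_by_event_date()`, same-date compositions joined with `+` as
multiple detected reactivities).

On the FHIR side the PLSC is the `code` of a `coding` under the
`plstring.org` system, code-system version `1.0`; the extractor accepts
both the standard `valueCodeableConcept` spelling and the
`valueCodableConcept` variant seen in circulating examples. On the HAML
side three fragment shapes are modelled — bead observation, assay
interpretation, diagnostic report — using only their published element
names with ASCII hyphens. The full HAML schema is still in development, so
this is a documented minimal profile, not a schema implementation; the
polarity of the two assay-interpretation PLSCs is carried in a
`specificities-type` element (`Positive`/`Negative`), reusing a published
element name rather than inventing one. `pl_convert()` moves a PLSC
between carriers byte-identically and reports carrier fields the other
side cannot hold (e.g. `bead-raw-data`) instead of dropping them silently.

## The generator, and what the tests do and do not show

Property tests and round-trip suites run on `pl_generate()` output:
expression trees drawn under a seeded RNG, descending the binding
hierarchy (a node's operands only use strictly tighter delimiters, since
the grammar has no parentheses), with heterodimer leaves drawn from the
vocabulary's pairing rules and an optional corruption mode that injects
GL-only delimiters or dangling operators for negative tests. Defaults
(depth ≤ 3, fan-out ≤ 3, 25% heterodimer leaves) produce strings of the
size and mix seen in the worked examples; the oracle suites use depth ≤ 2
and keep expressions to at most 10 atoms so the assignment-enumeration
oracle stays exact. The test suites run 10,000 such expressions against an
*independent* oracle that enumerates global truth assignments (one live
branch per XOR, one non-empty live subset per IOR) — a different algorithm
from the package's compositional evaluator — plus 1,000-string PLSC and
100-string carrier round-trips.

The generator emulates structural variety, not biological realism: it does
not model locus-plausible antigen co-occurrence, assay noise, vendor
formatting quirks beyond whitespace/Unicode hyphens, or real authority
vocabularies (the bundled tables are tiny). Passing tests demonstrate the
grammar, semantics and codecs are exact on their domain; they say nothing
about the clinical validity of any particular vocabulary or interpretation.

## Numerical and design choices

* World enumeration cap: 10^6 worlds (`EXPANSION_TOO_LARGE`), chosen to
  keep interactive use safe; all worked examples are orders of magnitude
  below it.
* Canonical ordering uses byte-wise (`radix`) sorting, so canonical output
  is locale-independent.
* Error handling is structured: every failure carries a short machine code
  (`GL_ONLY_DELIMITER`, `HETERODIMER_ARITY`, `UNKNOWN_ATOM`,
  `MALFORMED_PLSC`, ...) retrievable with `pl_error_code()`; the CLI maps
  them to exit code 1 and usage problems to 2.
* Eplet names are out of scope by design: their own registry has not
  standardised a syntax, and eplet spellings containing `+` would be
  ambiguous inside this grammar, so they are rejected as unknown atoms
  rather than special-cased. T-cell epitope and tetramer nomenclatures are
  likewise unsupported.

## Known limitations

Only the three published HAML fragment shapes are modelled, and
attribute-level details of the real HAML schema may differ once it is
released. The package never resolves a version token to an actual
vocabulary release; callers supply the matching table. Cross-namespace
antigen equivalence (e.g. DP105 versus DPB1*105:01) is loadable data, not
shipped logic.
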