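---
title: "Dictionary-driven CIF validation: model, checks and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-driven CIF validation: model, checks and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciflint)
```

## The validation model

A CIF file is a forest of data blocks holding *data items* (a data name
plus one value) and *looped lists* (a `loop_` grouping several data names
into packets of related values — the relational table of the format). A
DDL dictionary assigns each data name a definition: its type, category,
permitted values, loop eligibility and relations to other names.
Validation is the conjunction of per-value predicates (type, enumeration,
range, standard-uncertainty form) and relational predicates over loops
(key completeness and uniqueness, category homogeneity and integrity,
referential integrity). `ciflint` implements both generations of the
language:

* **DDL1** — types are only `numb`/`char`; keys come from
  `_list_reference`; parent/child links may be declared on either side;
  strings compare case-sensitively.
* **DDLm** — a rich content-type system (`Integer`, `Real`, `Date`,
  `DateTime`, `Symop`, `Uri`, ...), containers (`Single`, `List`,
  `Matrix`, `Table`), category classes (`Set` = unlooped singleton,
  `Loop` = relational table) with declared keys, alias tables, measurand
  purposes and per-type case rules.

Both suites run independently and never merge verdicts: when both
dictionaries are supplied, a file is validated twice and each finding
carries its originating suite. This mirrors curation practice, where the
two generations intentionally disagree in documented ways (case
sensitivity, artificial vs natural keys, partial-key treatment, type
formalization, containers, aliases); the test suite pins each of those
divergences as a named contract test.

Messages form a closed taxonomy of 25 semantic codes plus a small
reader-level set (syntax errors, duplicate data names, overlong lines,
non-ASCII bytes in CIF 1.1). Severity policy: parse failures are ERROR,
semantic violations WARNING, and advisory findings (deprecation,
unrecognized names, recommended-attribute absences) NOTE. Rendering is
one line per finding, `program: file(line) block: SEVERITY, detail`, and
is regression-locked: output is byte-identical across runs, and
permuting items or loop packets changes line numbers only.

## Tunable parameters

* `ignore_missing_su` (default `FALSE`) — suppresses only the
  missing-s.u. finding for measurands. Most legacy files were written
  before s.u. presence was mandated, so curators routinely disable this
  one check; it never affects the prohibited-s.u. or mismatching-s.u.
  findings.
* `report_deprecated` (default `FALSE`) — deprecated (replaced) items
  are tolerated by default; enabling adds NOTE-level findings naming the
  replacement, including the risky simultaneous presence of a replaced
  item and its replacement.
* `treat_as_set` (default `_atom_site_refinement_flags`) — the data
  names whose enumerated values are validated as *concatenations* of set
  members (greedy longest-match segmentation, ties broken by declaration
  order; for the classic single-letter flag set this reduces to
  per-character matching). Supplying the option replaces the default
  set, and the mode applies to both suites, since concatenation is a
  validator behaviour rather than a dictionary property.

Standard uncertainties follow the concise notation: in `12.5(3)` the
parenthesized digits scale to the last decimal place of the mantissa
(s.u. 0.3); with an exponent, the mantissa scaling applies first and the
exponent second, so `-1.234e-2(5)` has s.u. 5e-05 — the only reading
consistent with the notation's definition. For a measurand the lookup
order is concise notation first, then the linked s.u. item; both present
and unequal is a `mismatching_su`.

## Numerical and comparison choices

* Range bounds are inclusive on both sides; DDL1 character ranges are
  not evaluated (they do not occur in practice) and are flagged once at
  dictionary load.
* Normalized comparison (DDLm enumerations, keys, foreign keys, alias
  agreement) folds case for identifier-like types (`Code`, `Name`,
  `Tag`, `Symop`), canonicalizes numerals, and converts zoned `DateTime`
  values to UTC; a zone-less time stays floating and never equals a
  zoned one (no offset is invented). The mapping is idempotent, which
  the tests assert property-style.
* Content types degrade gracefully: a type name absent from the registry
  validates as `Text` (always ok), so dictionaries using unforeseen
  types remain usable.
* Special values — an unquoted `?` (unknown) or `.` (inapplicable) — are
  exempt from value-level checks and from foreign-key matching; the same
  characters in quotes are ordinary strings, a distinction the reader
  preserves via recorded quote styles.
* Duplicate data names in a block keep the last occurrence and emit a
  reader warning; dictionary name collisions keep the first definition.
  Conflicting DDL1 parent declarations resolve child-side-wins; cyclic
  parent chains are broken at the closing edge. All three rules are
  arbitrary but deterministic, which matters more here than the
  particular choice.
* DDLm category keys are declared with canonical ids while data files
  usually carry legacy alias names; key membership, s.u. pairing and
  foreign-key resolution are therefore alias-transparent throughout.
* A missing key item is silent when a dREL method could compute it
  (method execution itself is out of scope — only presence is detected),
  when a default value substitutes for it, or when its linked parent
  item is present in the same loop (the sparse child-category case);
  DDLm uniqueness is always evaluated over the key items actually
  present, whereas DDL1 skips uniqueness entirely on a partial key.
* Looped aliased values are not validated for agreement; the skipped
  definitions are reported on stderr and via the `skipped_aliases`
  attribute rather than as taxonomy messages, keeping the taxonomy
  closed and valid fixtures message-free.
* Dictionary application scope is checked only when the input is itself
  a DDLm dictionary and a reference dictionary is supplied (CLI flag
  `--ddlm-reference`); contexts are the top block (Dictionary) and each
  save frame (its declared scope).

## What the fixture generator emulates — and what it does not

`make_toy_dictionaries()` builds a mirrored DDL1/DDLm pair covering
every validated constraint: Set and Loop categories, simple and
composite keys (the bond category's key is extended by symmetry-site
items only in DDLm, as real core dictionaries do), a sparse parent/child
category pair, a measurand with a separate s.u. item, aliases (one
absent from the DDL1 dictionary), a deprecated item, a concatenated-set
item with states S, G, R, D, T, U, P, `.`, `List`/`Matrix` containers
and a dREL-method stub. The dictionaries are fixed study conditions and
do not vary with the seed; an import-split variant exercises the
embedded-import resolver.

`make_valid_cif(seed)` draws block sizes (3–6 atom sites, 2–4 symmetry
operators) and physically plausible values (cell length 5–25 Å with
s.u., occupancies in (0.5, 0.97] with s.u., bond distances 1.2–2.6 Å)
and is constructed to be message-free under both suites.
`inject_violations()` applies minimal, disjoint edits and records the
*exact* multiset of expected messages, including deliberate side effects
(splitting a loop to compromise category integrity necessarily also
produces missing-key findings), so soundness is asserted as exact
multiset equality, not containment.

The fixtures do not attempt to resemble real database entries
statistically: blocks are small, values are independent draws, and only
one data block per file is generated. Passing tests therefore
demonstrate the correctness of the checking logic under controlled
conditions, not robustness against the full heterogeneity of archived
CIF files (publisher templates, embedded text conventions, misspelt
data names — correction of which is a separate tool family and a
non-goal here).

## Problem sizes

The test and acceptance runs use 200 fixture seeds for the soundness
sweep, 100 random-loop trials of up to 200 packets for the brute-force
oracle comparisons (all-pairs duplicate scan; set-membership scan for
foreign keys), ten valid fixtures plus one fixture per taxonomy code for
the round-trip corpus, and differential option runs on a single combined
fixture. These sizes give every check multiple independent exercises
while keeping the default suite fast enough to run on every change.

## Known limitations

* dREL methods are detected, never executed; DDL2 dictionaries are not
  supported.
* DDLm compound values are checked structurally (container shape) but
  element-wise content typing inside lists/tables is limited to the
  Matrix row rule.
* Import resolution supports whole-frame (`Full`) merging; finer modes
  degrade to full with a warning.
* The rendered-message grammar restricts file labels to
  whitespace/colon/paren-free strings so that lines parse back
  unambiguously.
* Messages are deduplicated only within a suite; the same underlying
  problem found by both suites is reported twice, once per suite — a
  deliberate choice, since the two ontologies are distinct authorities.
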