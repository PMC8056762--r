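# ciflint

Dictionary-driven semantic validation of Crystallographic Information
Framework (CIF) files in R.

Crystallographic data travel as CIF files: STAR-derived text files whose
*data items* (`_cell_length_a 10.45(3)`) and *looped lists* (`loop_`
tables) are described, relationally and semantically, by separate
ontology dictionaries written in the Dictionary Definition Language —
the legacy DDL1 generation and the current, relationally richer DDLm
generation. Open crystallographic databases curate hundreds of thousands
of such files, and most quality problems are not syntax errors but
semantic ones: values outside enumeration sets, misplaced standard
uncertainties, broken composite keys, foreign-key values with no parent,
free text where a structured list is required.

`ciflint` is for data curators, dictionary maintainers and
crystallographic software developers who need those problems surfaced
mechanically. It provides:

* a reader/writer for CIF 1.1 and CIF 2.0 (lists, tables, triple-quoted
  strings, save frames), error-correcting where safe and position-exact
  where not;
* loaders for DDL1 dictionaries and DDLm dictionaries (with embedded
  import resolution, alias tables, category trees and keys);
* the two validation suites. Writing a category key as the composite
  primary key K(C) of category C, the key check asserts that each key
  item of K(C) is present in C's loop and that the normalized key tuples
  are pairwise distinct; referential integrity asserts
  values(child) ⊆ values(parent) for every declared parent–child (foreign
  key) link; value checks cover content types (Integer, Real, Date,
  DateTime, Symop, Uri, ...), enumeration sets (including legacy
  *concatenated* sets such as the refinement-flag values `PDU`, `PR`),
  permitted ranges, and the concise standard-uncertainty notation
  `12.5(3)` in which the parenthesized digits scale to the last decimal
  place of the mantissa;
* a closed, machine-parsable message taxonomy with NOTE / WARNING /
  ERROR severities, rendered one finding per line for Unix-filter use;
* a deterministic fixture generator that builds a mirrored toy DDL1/DDLm
  dictionary pair and CIF files with seeded violations together with the
  exact message multiset a correct validator must emit.

## Worked example

```r
library(ciflint)
toy <- make_toy_dictionaries()
dicts <- load_toy_dictionaries(toy)

cif <- c("data_demo",
         "_cell_setting Monoclinic",
         "_cell_length_a 10.4",
         "_chemical_melting_point '24 C'",
         "loop_",
         "_symmetry_equiv_pos_site_id",
         "_symmetry_equiv_pos_as_xyz",
         "1 x,y,z",
         "2 x,y,z")

doc <- parse_cif(cif, file = "demo.cif")
msgs <- validate_document(doc, ddl1 = dicts$ddl1, ddlm = dicts$ddlm)
writeLines(vapply(msgs, render_message, character(1)))
```

```
ciflint: demo.cif(2) data_demo: WARNING, value 'Monoclinic' of _cell_setting is outside the enumeration set
ciflint: demo.cif(3) data_demo: WARNING, measurand _cell_length_a lacks a standard uncertainty
ciflint: demo.cif(4) data_demo: WARNING, value '24 C' of _chemical_melting_point is not numeric
ciflint: demo.cif(4) data_demo: WARNING, value '24 C' of _chemical_melting_point violates the Real content type
ciflint: demo.cif(5) data_demo: WARNING, duplicate key value (x,y,z) for (_symmetry_equiv_pos_as_xyz) in a looped list
```

Reading the output: DDL1 enumeration comparison is case-sensitive, so
`Monoclinic` is rejected while DDLm (whose `Code` type folds case) stays
silent — the first line is a DDL1 finding. `_cell_length_a` is a DDLm
*measurand*, so a value without a standard uncertainty in either the
concise notation (`10.4(2)`) or a separate s.u. item is flagged
(suppressible with `ignore_missing_su`). The melting-point value `24 C`
fails as DDL1 `numb` and as DDLm `Real` — one finding per suite. The
duplicated symmetry operator is caught by the DDL1 natural key on the
operator string; DDLm keys that category by an artificial integer id, so
only the DDL1 suite reports it.

The same run is available as a command-line filter
(`inst/scripts/cif_validate.R`): messages to stdout, diagnostics to
stderr, exit 0 when every input was processed (findings are data, not
failure), 1 on parse/dictionary failure, 2 on usage error. The flags
`--ignore-missing-su`, `--report-deprecated` and `--treat-as-set` mirror
the validator options.

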