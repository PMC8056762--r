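# small data blocks are parsed from text against the toy dictionaries
d1_run <- function(lines, fun = validate_block_ddl1,
                   opts = cif_validation_options()) {
  fun(first_block(c("data_t", lines)), toy_dicts$ddl1, opts)
}

test_that("numb items reject non-numeric values and unexpected s.u.", {
  ms <- d1_run("_chemical_melting_point '24 C'", d1_check_values)
  expect_equal(codes_of(ms), "non_numeric_value")

  ms <- d1_run("_cell_volume 1234.5(3)", d1_check_values)
  expect_equal(codes_of(ms), "extra_su")

  # s.u.-eligible items carry concise s.u. silently
  expect_length(d1_run("_cell_length_a 10.5(3)", d1_check_values), 0L)

  # special values are exempt from all value checks
  expect_length(d1_run(c("_chemical_melting_point ?",
                         "_cell_setting ."), d1_check_values), 0L)
})

test_that("DDL1 enumerations compare case-sensitively", {
  ms <- d1_run("_cell_setting Monoclinic", d1_check_values)
  expect_equal(codes_of(ms), "value_outside_enum")
  expect_length(d1_run("_cell_setting monoclinic", d1_check_values), 0L)
})

test_that("ranges are inclusive on both bounds", {
  loop_occ <- function(v) c("loop_", "_atom_site_label",
                            "_atom_site_occupancy", paste("C1", v))
  expect_length(d1_run(loop_occ("1.0"), d1_check_values), 0L)
  expect_length(d1_run(loop_occ("0.0"), d1_check_values), 0L)
  expect_equal(codes_of(d1_run(loop_occ("1.01"), d1_check_values)),
               "value_outside_range")
})

test_that("looped-list eligibility follows the yes/no/both states", {
  ms <- d1_run("_atom_site_label C1", d1_check_loop_membership)
  expect_equal(codes_of(ms), "looped_value_outside_loop")

  ms <- d1_run(c("loop_", "_cell_setting", "monoclinic"),
               d1_check_loop_membership)
  expect_equal(codes_of(ms), "unlooped_value_in_loop")
})

test_that("loop keys must be present and unique; partial keys skip uniqueness", {
  dup <- d1_run(c("loop_", "_symmetry_equiv_pos_site_id",
                  "_symmetry_equiv_pos_as_xyz",
                  "1 x,y,z", "2 x,y,z"), d1_check_loop_keys)
  expect_equal(codes_of(dup), "nonunique_simple_key")

  # composite key with one member absent: missing item only, no uniqueness
  partial <- d1_run(c("loop_", "_geom_bond_atom_site_label_1",
                      "_geom_bond_distance",
                      "C1 1.5", "C1 1.6"), d1_check_loop_keys)
  expect_equal(codes_of(partial), "missing_key_item")
  expect_equal(partial[[1]]$subjects, "_geom_bond_atom_site_label_2")

  complete <- d1_run(c("loop_", "_geom_bond_atom_site_label_1",
                       "_geom_bond_atom_site_label_2",
                       "C1 C2", "C1 C3"), d1_check_loop_keys)
  expect_length(complete, 0L)
})

test_that("reference groups must stay in one loop and loops stay homogeneous", {
  split <- d1_run(c("loop_", "_geom_bond_atom_site_label_1",
                    "_geom_bond_atom_site_label_2", "C1 C2",
                    "loop_", "_geom_bond_distance", "1.5"),
                  d1_check_loop_integrity)
  expect_equal(codes_of(split), "compromised_category_integrity")

  mixed <- d1_run(c("loop_", "_cell_setting", "_atom_site_label",
                    "monoclinic C1"), d1_check_loop_integrity)
  expect_equal(codes_of(mixed), "mixed_category_loop")

  clean <- d1_run(c("loop_", "_atom_site_label", "_atom_site_occupancy",
                    "C1 0.5(1)", "C2 0.6(1)"), d1_check_loop_integrity)
  expect_length(clean, 0L)
})

test_that("referential integrity is case-sensitive under DDL1", {
  base <- c("loop_", "_atom_site_label", "C1", "C2")
  ok <- d1_run(c(base, "loop_", "_geom_bond_atom_site_label_1",
                 "_geom_bond_atom_site_label_2", "C1 C2"),
               d1_check_referential_integrity)
  expect_length(ok, 0L)

  value_missing <- d1_run(c(base, "loop_",
                            "_geom_bond_atom_site_label_1",
                            "_geom_bond_atom_site_label_2", "C1 c2"),
                          d1_check_referential_integrity)
  expect_equal(codes_of(value_missing), "missing_foreign_key_value")

  item_missing <- d1_run(c("loop_", "_geom_bond_atom_site_label_1",
                           "_geom_bond_atom_site_label_2", "C1 C2"),
                         d1_check_referential_integrity)
  expect_equal(sort(codes_of(item_missing)),
               rep("missing_foreign_key_item", 2L))

  # parent values need not be unique; special child values are exempt
  specials <- d1_run(c("loop_", "_atom_site_label", "C1", "C1",
                       "loop_", "_geom_bond_atom_site_label_1",
                       "_geom_bond_atom_site_label_2", "C1 ?"),
                     d1_check_referential_integrity)
  expect_length(specials, 0L)
})

test_that("deprecation is reported only when enabled", {
  lines <- "_chemical_formula_weight_meas 240.3"
  expect_length(d1_run(lines, d1_check_deprecation), 0L)

  on <- cif_validation_options(report_deprecated = TRUE)
  ms <- d1_run(lines, d1_check_deprecation, opts = on)
  expect_equal(codes_of(ms), "deprecated_item")
  expect_equal(ms[[1]]$severity, "NOTE")

  both <- d1_run(c(lines, "_chemical_formula_weight 240.3"),
                 d1_check_deprecation, opts = on)
  expect_match(both[[1]]$detail, "simultaneous presence")
})

test_that("mandatory loop items and declared uniqueness sets are enforced", {
  ms <- d1_run(c("loop_", "_symmetry_equiv_pos_as_xyz",
                 "x,y,z", "-x,-y,-z"),
               d1_check_mandatory_and_uniqueness)
  expect_equal(codes_of(ms), "missing_mandatory_loop_item")
  expect_equal(ms[[1]]$subjects, "_symmetry_equiv_pos_site_id")

  dup_id <- d1_run(c("loop_", "_symmetry_equiv_pos_site_id",
                     "_symmetry_equiv_pos_as_xyz",
                     "1 x,y,z", "1 -x,-y,-z"),
                   d1_check_mandatory_and_uniqueness)
  expect_equal(codes_of(dup_id), "nonunique_composite_key")

  clean <- d1_run(c("loop_", "_symmetry_equiv_pos_site_id",
                    "_symmetry_equiv_pos_as_xyz",
                    "1 x,y,z", "2 -x,-y,-z"),
                  d1_check_mandatory_and_uniqueness)
  expect_length(clean, 0L)
})

test_that("names unknown to every supplied dictionary are noted", {
  b <- first_block(c("data_t", "_not_a_real_tag 5",
                     "_symmetry_cell_setting monoclinic",
                     "_cell_volume 10."))
  ddl1_only <- check_unrecognized(b, list(toy_dicts$ddl1))
  expect_equal(sort(unlist(lapply(ddl1_only, function(m) m$subjects))),
               c("_not_a_real_tag", "_symmetry_cell_setting"))
  with_ddlm <- check_unrecognized(b, list(toy_dicts$ddl1, toy_dicts$ddlm))
  expect_equal(unlist(lapply(with_ddlm, function(m) m$subjects)),
               "_not_a_real_tag")
  expect_true(all(vapply(with_ddlm, function(m) m$severity, character(1))
                  == "NOTE"))
})

test_that("the concatenated-set mode applies to DDL1 validation too", {
  loop_flags <- function(v) c("loop_", "_atom_site_label",
                              "_atom_site_refinement_flags",
                              paste("C1", v))
  expect_length(d1_run(loop_flags("PDU"), d1_check_values), 0L)
  expect_equal(codes_of(d1_run(loop_flags("PXU"), d1_check_values)),
               "value_outside_enum")
})
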