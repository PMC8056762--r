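m_run <- function(lines, fun = validate_block_ddlm,
                  opts = cif_validation_options(), dict = toy_dicts$ddlm) {
  fun(first_block(c("#\\#CIF_2.0", "data_t", lines), dialect = "cif20"),
      dict, opts)
}

test_that("content-type findings carry the violated type kind", {
  ms <- m_run("_cell_formula_units_z 4.0", m_check_values)
  expect_equal(codes_of(ms), "type_violation")
  expect_equal(ms[[1]]$type_kind, "Integer")

  ms <- m_run("_audit_creation_date 2021-13-01", m_check_values)
  expect_equal(ms[[1]]$type_kind, "Date")

  ms <- m_run("_cod_database_code '12 34'", m_check_values)
  expect_equal(codes_of(ms), "forbidden_symbol")

  expect_length(m_run(c("_cell_formula_units_z 4",
                        "_audit_creation_date 2021-12-01",
                        "_cod_database_code 1234567"), m_check_values), 0L)
})

test_that("measurands need an s.u. in one of the two notations", {
  expect_equal(codes_of(m_run("_cell_length_a 10.0", m_check_values)),
               "missing_su")
  expect_length(m_run("_cell_length_a 10.0(2)", m_check_values), 0L)
  expect_length(m_run(c("_cell_length_a 10.0",
                        "_cell_length_a_su 0.02"), m_check_values), 0L)

  silent <- cif_validation_options(ignore_missing_su = TRUE)
  expect_length(m_run("_cell_length_a 10.0", m_check_values, opts = silent),
                0L)
})

test_that("s.u. on a non-measurand is prohibited; disagreement is flagged", {
  expect_equal(codes_of(m_run("_cell_volume 1234.5(3)", m_check_values)),
               "prohibited_su")
  ms <- m_run(c("_cell_length_a 10.00(2)", "_cell_length_a_su 0.03"),
              m_check_values)
  expect_equal(codes_of(ms), "mismatching_su")
  expect_length(m_run(c("_cell_length_a 10.00(2)",
                        "_cell_length_a_su 0.02"), m_check_values), 0L)
})

test_that("type-aware enumeration comparison folds case for Code values", {
  expect_length(m_run("_cell_setting Monoclinic", m_check_values), 0L)
  expect_equal(codes_of(m_run("_cell_setting cubic", m_check_values)),
               "value_outside_enum")
})

test_that("concatenated enumeration sets accept combinations by default", {
  flags <- function(v) c("loop_", "_atom_site_label",
                         "_atom_site_occupancy",
                         "_atom_site_refinement_flags",
                         paste("C1 0.5(1)", v))
  for (v in c("PDU", "PR", "DUP", "S"))
    expect_length(m_run(flags(v), m_check_values), 0L)
  expect_equal(codes_of(m_run(flags("PXU"), m_check_values)),
               "value_outside_enum")
})

test_that("the concatenated-set mode transfers to any supplied name", {
  transferred <- cif_validation_options(treat_as_set = "_cell_setting")
  expect_length(m_run("_cell_setting triclinicmonoclinic", m_check_values,
                      opts = transferred), 0L)
  expect_equal(codes_of(m_run("_cell_setting triclinicX", m_check_values,
                              opts = transferred)), "value_outside_enum")
  # the option replaces the default set: the flags item reverts to a
  # plain enumeration under which concatenations are outside the set
  flags <- c("loop_", "_atom_site_label", "_atom_site_occupancy",
             "_atom_site_refinement_flags", "C1 0.5(1) PDU")
  expect_true("value_outside_enum" %in%
                codes_of(m_run(flags, m_check_values, opts = transferred)))
})

test_that("containers must match the declared data structure", {
  ms <- m_run(c("_atom_type_scat_versus_stol_list",
                ";0.1 1.2", "0.3 0.9", ";"), m_check_container)
  expect_equal(codes_of(ms), "missing_top_level_container")

  expect_length(m_run("_atom_type_scat_versus_stol_list [0.1 0.3]",
                      m_check_container), 0L)
  expect_length(m_run("_cell_metric_tensor [[1. 0.] [0. 1.]]",
                      m_check_container), 0L)
  ms <- m_run("_cell_metric_tensor [1. 0. 0.]", m_check_container)
  expect_equal(codes_of(ms), "value_not_in_list")

  ms <- m_run("_cell_volume [1 2]", m_check_container)
  expect_equal(codes_of(ms), "missing_top_level_container")
})

test_that("Set-category items are barred from loops; Loop items may be unlooped", {
  ms <- m_run(c("loop_", "_cell_length_a", "10.0(3)"), m_check_loop_class)
  expect_equal(codes_of(ms), "unlooped_value_in_loop")
  # a single unlooped Loop-class item reads as a one-packet loop
  expect_length(m_run("_atom_site_label C1", validate_block_ddlm), 0L)
})

test_that("category integrity allows the sparse child inside the parent loop", {
  child_in_parent <- m_run(
    c("loop_", "_atom_site_label", "_atom_site_aniso_label",
      "_atom_site_aniso_u_11", "C1 C1 0.05(1)"),
    m_check_category_integrity)
  expect_length(child_in_parent, 0L)

  split <- m_run(c("loop_", "_atom_site_label", "C1",
                   "loop_", "_atom_site_occupancy", "0.5(1)"),
                 m_check_category_integrity)
  expect_equal(codes_of(split), "compromised_category_integrity")

  mixed <- m_run(c("loop_", "_atom_site_label", "_atom_type_symbol",
                   "C1 C"), m_check_category_integrity)
  expect_equal(codes_of(mixed), "mixed_category_loop")
})

test_that("category keys honour methods, defaults and linked parents", {
  # the symmetry id item has a dREL method: its absence is silent
  expect_length(m_run(c("loop_", "_symmetry_equiv_pos_as_xyz",
                        "x,y,z", "-x,-y,-z"), m_check_category_keys), 0L)

  # a key item with a default contributes it silently (mini dictionary)
  mini <- mini_ddlm(
    c("save_T", "_definition.id T", "_definition.scope Category",
      "_definition.class Loop",
      "loop_", "_category_key.name", "'_t.id'", "'_t.flag'", "save_",
      "save_t.id", "_definition.id '_t.id'", "_name.category_id t",
      "_name.object_id id", "_type.contents Code", "save_",
      "save_t.flag", "_definition.id '_t.flag'", "_name.category_id t",
      "_name.object_id flag", "_type.contents Code",
      "_enumeration.default none", "save_",
      "save_t.value", "_definition.id '_t.value'", "_name.category_id t",
      "_name.object_id value", "_type.contents Real", "save_"))
  clean <- m_run(c("loop_", "_t.id", "_t.value", "a 1.0", "b 2.0"),
                 m_check_category_keys, dict = mini)
  expect_length(clean, 0L)

  # without default or method the absent key item is reported
  absent <- m_run(c("loop_", "_t.flag", "_t.value", "x 1.0", "y 2.0"),
                  m_check_category_keys, dict = mini)
  expect_equal(codes_of(absent), "missing_key_item")
  expect_equal(absent[[1]]$subjects, "_t.id")

  # the aniso child key links to a parent item present in the same loop
  expect_length(m_run(
    c("loop_", "_atom_site_label", "_atom_site_aniso_u_11",
      "C1 0.05(1)"), m_check_category_keys), 0L)
})

test_that("DDLm always checks uniqueness over the present key items", {
  partial_dup <- m_run(c("loop_", "_geom_bond_atom_site_label_1",
                         "_geom_bond_distance",
                         "C1 1.5(1)", "C1 1.6(1)"), m_check_category_keys)
  expect_true("nonunique_simple_key" %in% codes_of(partial_dup))
  expect_true("missing_key_item" %in% codes_of(partial_dup))

  # normalized comparison: Code keys fold case, so C1 and c1 collide
  norm_dup <- m_run(c("loop_", "_atom_site_label", "_atom_site_occupancy",
                      "C1 0.5(1)", "c1 0.6(1)"), m_check_category_keys)
  expect_equal(codes_of(norm_dup), "nonunique_simple_key")
})

test_that("DDLm referential integrity matches values after normalization", {
  base <- c("loop_", "_atom_site_label", "C1", "C2")
  folded <- m_run(c(base, "loop_", "_geom_bond_atom_site_label_1",
                    "_geom_bond_atom_site_label_2",
                    "_geom_bond_site_symmetry_1",
                    "_geom_bond_site_symmetry_2",
                    "_geom_bond_distance",
                    "c1 C2 1_555 1_555 1.5(1)"),
                  m_check_referential_integrity)
  expect_length(folded, 0L)

  missing <- m_run(c(base, "loop_", "_geom_bond_atom_site_label_1",
                     "_geom_bond_atom_site_label_2",
                     "_geom_bond_site_symmetry_1",
                     "_geom_bond_site_symmetry_2",
                     "_geom_bond_distance",
                     "Q9 C2 1_555 1_555 1.5(1)"),
                   m_check_referential_integrity)
  expect_equal(codes_of(missing), "missing_foreign_key_value")
})

test_that("aliased unlooped values must agree after normalization", {
  ms <- m_run(c("_cell_setting monoclinic",
                "_symmetry_cell_setting triclinic"), m_check_aliases)
  expect_equal(codes_of(ms), "alias_value_mismatch")

  expect_length(m_run(c("_cell_setting Monoclinic",
                        "_symmetry_cell_setting monoclinic"),
                      m_check_aliases), 0L)

  looped <- m_run(c("_cell_setting monoclinic",
                    "loop_", "_symmetry_cell_setting", "triclinic"),
                  m_check_aliases)
  expect_length(looped, 0L)
  expect_equal(attr(looped, "skipped_aliases"), "_cell.setting")
})

test_that("DDLm deprecation notes name the replacement", {
  lines <- "_chemical_formula_weight_meas 240.3"
  expect_length(m_run(lines, m_check_deprecation), 0L)
  on <- cif_validation_options(report_deprecated = TRUE)
  ms <- m_run(lines, m_check_deprecation, opts = on)
  expect_equal(codes_of(ms), "deprecated_item")
  expect_true("_chemical.formula_weight" %in% ms[[1]]$subjects)
  # the replacement itself is not deprecated
  expect_length(m_run("_chemical_formula_weight 240.3",
                      m_check_deprecation, opts = on), 0L)
})

test_that("application scope is checked only for dictionary files", {
  clean <- validate_ddlm_dictionary(toy_dicts$ddlm_doc,
                                    toy_dicts$reference_doc)
  expect_length(clean, 0L)

  txt <- toy$ddlm_text
  broken <- parse_cif(txt[!grepl("_dictionary.date", txt, fixed = TRUE)])
  ms <- validate_ddlm_dictionary(broken, toy_dicts$reference_doc)
  expect_equal(codes_of(ms), "scope_violation")
  expect_equal(ms[[1]]$subjects, "_dictionary.date")

  # a prohibited attribute inside an Item frame is flagged
  idx <- which(grepl("_definition.id '_cell.volume'", txt, fixed = TRUE))
  txt2 <- append(txt, "    _dictionary.title WRONG", after = idx)
  ms2 <- validate_ddlm_dictionary(parse_cif(txt2),
                                  toy_dicts$reference_doc)
  expect_equal(codes_of(ms2), "scope_violation")
  expect_match(ms2[[1]]$detail, "prohibited")

  # an ordinary data file run never produces scope findings
  m <- make_valid_cif(2)
  ms3 <- validate_document(parse_cif(m$cif_text), toy_dicts$ddl1,
                           toy_dicts$ddlm)
  expect_false("scope_violation" %in% codes_of(ms3))
})
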