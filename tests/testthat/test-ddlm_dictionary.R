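test_that("the toy DDLm dictionary loads without warnings", {
  expect_length(toy_dicts$ddlm$warnings, 0L)
  expect_gt(length(toy_dicts$ddlm$defs), 40L)
})

test_that("aliases resolve to the same definition as the canonical id", {
  d <- toy_dicts$ddlm
  for (nm in names(d$defs)) {
    def <- d$defs[[nm]]
    expect_identical(lookup_ddlm(d, nm)$id, lookup_ddlm(d, def$id)$id)
  }
  expect_identical(lookup_ddlm(d, "_symmetry_cell_setting")$id,
                   "_cell.setting")
  expect_identical(lookup_ddlm(d, "_CELL_LENGTH_A")$id, "_cell.length_a")
})

test_that("category tree, classes and keys load", {
  d <- toy_dicts$ddlm
  expect_equal(d$categories[["cell"]]$class, "Set")
  expect_equal(d$categories[["atom_site"]]$class, "Loop")
  expect_equal(key_of(d, "ATOM_SITE"), "_atom_site.label")
  expect_equal(key_of(d, "geom_bond"),
               c("_geom_bond.atom_site_label_1",
                 "_geom_bond.atom_site_label_2",
                 "_geom_bond.site_symmetry_1",
                 "_geom_bond.site_symmetry_2"))
  expect_equal(key_of(d, "symmetry_equiv"), "_symmetry_equiv.pos_site_id")
  expect_equal(category_of(d, "_cell_length_a")$id, "cell")
})

test_that("su links invert into the measurand table", {
  expect_equal(toy_dicts$ddlm$su_of[["_cell.length_a"]],
               "_cell.length_a_su")
})

test_that("a Loop category keyed into another Loop category is its child", {
  expect_equal(toy_dicts$ddlm$child_of[["atom_site_aniso"]], "atom_site")
  expect_null(toy_dicts$ddlm$child_of[["geom_bond"]])
})

test_that("dREL method presence is detected", {
  expect_true(lookup_ddlm(toy_dicts$ddlm,
                          "_symmetry_equiv.pos_site_id")$has_method)
  expect_false(lookup_ddlm(toy_dicts$ddlm, "_cell.length_a")$has_method)
})

test_that("two frames claiming one alias fail to load", {
  expect_error(mini_ddlm(
    c("save_a", "_definition.id '_a.x'", "_name.category_id a",
      "_name.object_id x", "loop_", "_alias.definition_id", "'_shared'",
      "save_",
      "save_b", "_definition.id '_b.y'", "_name.category_id b",
      "_name.object_id y", "loop_", "_alias.definition_id", "'_shared'",
      "save_")),
    "claimed by two definitions")
})

test_that("imports merge frames with local definitions winning", {
  locator <- function(nm)
    if (nm == "toy_ext.dic") parse_cif(toy$ddlm_import_ext_text) else NULL
  main <- resolve_imports(parse_cif(toy$ddlm_import_main_text), locator)
  d <- load_ddlm(main)
  expect_false(is.null(lookup_ddlm(d, "_cod_database_code")))
  expect_equal(category_of(d, "_database.cod_code")$class, "Set")
  # the merged dictionary equals the self-contained one on shared names
  expect_equal(sort(names(d$defs)), sort(names(toy_dicts$ddlm$defs)))
})

test_that("a self-import is detected as a cycle", {
  txt <- c("#\\#CIF_2.0", "data_self",
           "save_h", "_definition.id H", "_definition.scope Category",
           "_definition.class Head",
           "_import.get [{'file':'self.dic' 'save':'h'}]",
           "save_")
  locator <- function(nm) if (nm == "self.dic") parse_cif(txt) else NULL
  expect_error(resolve_imports(parse_cif(txt), locator,
                               .stack = "self.dic"),
               "cycle")
})

test_that("a missing import target warns or fails according to policy", {
  locator <- function(nm) NULL
  doc <- parse_cif(toy$ddlm_import_main_text)
  expect_error(resolve_imports(doc, locator, missing_policy = "fail"),
               "cannot be located")
  merged <- resolve_imports(doc, locator, missing_policy = "warn")
  expect_true(any(grepl("cannot be located",
                        vapply(merged$warnings, function(w) w$detail,
                               character(1)))))
})

test_that("non-full import modes degrade to full with a warning", {
  ext <- c("#\\#CIF_2.0", "data_e",
           "save_x", "_definition.id '_e.x'", "_name.category_id e",
           "_name.object_id x", "save_")
  main <- c("#\\#CIF_2.0", "data_m",
            "save_h", "_definition.id H", "_definition.scope Category",
            "_definition.class Head",
            "_import.get [{'file':'e.dic' 'save':'x' 'mode':'Contents'}]",
            "save_")
  locator <- function(nm) if (nm == "e.dic") parse_cif(ext) else NULL
  merged <- resolve_imports(parse_cif(main), locator)
  expect_true(any(grepl("treated as Full",
                        vapply(merged$warnings, function(w) w$detail,
                               character(1)))))
  expect_false(is.null(lookup_ddlm(load_ddlm(merged), "_e.x")))
})
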