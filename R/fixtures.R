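#' @title Fixture generator
#' @description Deterministic generator of a mirrored toy DDL1/DDLm
#'   dictionary pair, valid CIF files exercising every category, and
#'   seeded violations together with the exact multiset of messages a
#'   correct validator must emit. This is the package's primary test
#'   surface: fixtures are built in code at run time, never stored.
#' @name fixtures
NULL

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# ---- toy dictionaries ----------------------------------------------------

toy_ddl1_def <- function(block, name, category, type, extra = character()) {
  c(sprintf("data_%s", block),
    sprintf("    _name '%s'", name),
    sprintf("    _category %s", category),
    sprintf("    _type %s", type),
    paste0("    ", extra),
    "")
}

toy_ddl1_text <- function() {
  c("data_on_this_dictionary",
    "    _dictionary_name cif_toy.dic",
    "    _dictionary_version 1.0",
    "",
    toy_ddl1_def("cell_length_a", "_cell_length_a", "cell", "numb",
                 c("_type_conditions esu", "_enumeration_range 0.0:",
                   "_list no")),
    toy_ddl1_def("cell_length_a_su", "_cell_length_a_su", "cell", "numb",
                 "_list no"),
    toy_ddl1_def("cell_volume", "_cell_volume", "cell", "numb",
                 c("_enumeration_range 0.0:", "_list no")),
    toy_ddl1_def("cell_formula_units_z", "_cell_formula_units_z", "cell",
                 "numb", c("_enumeration_range 1:", "_list no")),
    c("data_cell_setting",
      "    _name '_cell_setting'",
      "    _category cell",
      "    _type char",
      "    _list no",
      "    loop_ _enumeration",
      "    triclinic monoclinic orthorhombic",
      ""),
    toy_ddl1_def("cell_metric_tensor", "_cell_metric_tensor", "cell",
                 "char", "_list no"),
    toy_ddl1_def("chemical_formula_weight", "_chemical_formula_weight",
                 "chemical", "numb",
                 c("_enumeration_range 1.0:", "_list no")),
    toy_ddl1_def("chemical_formula_weight_meas",
                 "_chemical_formula_weight_meas", "chemical", "numb",
                 c("_list no", "_related_item '_chemical_formula_weight'",
                   "_related_function replace")),
    toy_ddl1_def("chemical_melting_point", "_chemical_melting_point",
                 "chemical", "numb",
                 c("_enumeration_range 0.0:", "_list no")),
    toy_ddl1_def("cod_database_code", "_cod_database_code", "database",
                 "char", "_list no"),
    toy_ddl1_def("audit_creation_date", "_audit_creation_date", "audit",
                 "char", "_list no"),
    toy_ddl1_def("symmetry_equiv_pos_as_xyz", "_symmetry_equiv_pos_as_xyz",
                 "symmetry_equiv", "char",
                 c("_list yes",
                   "_list_reference '_symmetry_equiv_pos_as_xyz'",
                   "_list_uniqueness '_symmetry_equiv_pos_site_id'")),
    toy_ddl1_def("symmetry_equiv_pos_site_id",
                 "_symmetry_equiv_pos_site_id", "symmetry_equiv", "numb",
                 c("_list yes", "_list_mandatory yes")),
    toy_ddl1_def("atom_site_label", "_atom_site_label", "atom_site", "char",
                 c("_list yes", "_list_reference '_atom_site_label'")),
    toy_ddl1_def("atom_site_type_symbol", "_atom_site_type_symbol",
                 "atom_site", "char",
                 c("_list yes", "_list_reference '_atom_site_label'",
                   "_list_link_parent '_atom_type_symbol'")),
    toy_ddl1_def("atom_site_occupancy", "_atom_site_occupancy", "atom_site",
                 "numb",
                 c("_type_conditions esu", "_enumeration_range 0.0:1.0",
                   "_list yes", "_list_reference '_atom_site_label'")),
    c("data_atom_site_refinement_flags",
      "    _name '_atom_site_refinement_flags'",
      "    _category atom_site",
      "    _type char",
      "    _list yes",
      "    _list_reference '_atom_site_label'",
      "    loop_ _enumeration",
      "    S G R D T U P '.'",
      ""),
    toy_ddl1_def("atom_site_aniso_label", "_atom_site_aniso_label",
                 "atom_site_aniso", "char",
                 c("_list yes", "_list_reference '_atom_site_aniso_label'",
                   "_list_link_parent '_atom_site_label'")),
    toy_ddl1_def("atom_site_aniso_u_11", "_atom_site_aniso_u_11",
                 "atom_site_aniso", "numb",
                 c("_type_conditions esu", "_list yes",
                   "_list_reference '_atom_site_aniso_label'")),
    toy_ddl1_def("atom_type_symbol", "_atom_type_symbol", "atom_type",
                 "char",
                 c("_list yes", "_list_reference '_atom_type_symbol'",
                   "_list_link_child '_atom_site_type_symbol'")),
    toy_ddl1_def("atom_type_scat_versus_stol_list",
                 "_atom_type_scat_versus_stol_list", "atom_type", "char",
                 c("_list yes", "_list_reference '_atom_type_symbol'")),
    c("data_geom_bond_atom_site_label_",
      "    loop_ _name",
      "    '_geom_bond_atom_site_label_1'",
      "    '_geom_bond_atom_site_label_2'",
      "    _category geom_bond",
      "    _type char",
      "    _list yes",
      "    loop_ _list_reference",
      "    '_geom_bond_atom_site_label_1'",
      "    '_geom_bond_atom_site_label_2'",
      "    _list_link_parent '_atom_site_label'",
      ""),
    c("data_geom_bond_site_symmetry_",
      "    loop_ _name",
      "    '_geom_bond_site_symmetry_1'",
      "    '_geom_bond_site_symmetry_2'",
      "    _category geom_bond",
      "    _type char",
      "    _list yes",
      "    loop_ _list_reference",
      "    '_geom_bond_atom_site_label_1'",
      "    '_geom_bond_atom_site_label_2'",
      ""),
    c("data_geom_bond_distance",
      "    _name '_geom_bond_distance'",
      "    _category geom_bond",
      "    _type numb",
      "    _type_conditions esu",
      "    _enumeration_range 0.0:",
      "    _list yes",
      "    loop_ _list_reference",
      "    '_geom_bond_atom_site_label_1'",
      "    '_geom_bond_atom_site_label_2'",
      ""))
}

toy_ddlm_frame <- function(id, cat, obj, contents = "Text",
                           purpose = "Describe", container = "Single",
                           aliases = character(), extra = character()) {
  code <- sub("^_", "", id)
  alias_lines <- if (length(aliases))
    c("    loop_", "    _alias.definition_id",
      sprintf("        '%s'", aliases)) else character()
  c(sprintf("save_%s", code),
    sprintf("    _definition.id '%s'", id),
    "    _definition.scope Item",
    "    _definition.class Datum",
    sprintf("    _name.category_id %s", cat),
    sprintf("    _name.object_id %s", obj),
    sprintf("    _type.contents %s", contents),
    sprintf("    _type.purpose %s", purpose),
    sprintf("    _type.container %s", container),
    "    _description.text",
    ";    toy definition",
    ";",
    alias_lines,
    paste0("    ", extra),
    "save_",
    "")
}

toy_ddlm_category <- function(id, class, keys = character(),
                              parent = "toy_head", extra = character()) {
  key_lines <- if (length(keys))
    c("    loop_", "    _category_key.name",
      sprintf("        '%s'", keys)) else character()
  c(sprintf("save_%s", id),
    sprintf("    _definition.id %s", id),
    "    _definition.scope Category",
    sprintf("    _definition.class %s", class),
    sprintf("    _name.category_id %s", parent),
    sprintf("    _name.object_id %s", id),
    "    _description.text",
    ";    toy category",
    ";",
    key_lines,
    if (length(extra)) paste0("    ", extra),
    "save_",
    "")
}

toy_ddlm_body <- function(with_database = TRUE, import_head = FALSE) {
  head_extra <- if (import_head)
    "_import.get [{'file':'toy_ext.dic' 'save':'DATABASE'} {'file':'toy_ext.dic' 'save':'database.cod_code'}]"
  else character()
  c(toy_ddlm_category("TOY_HEAD", "Head", parent = "toy_dic",
                      extra = head_extra),
    toy_ddlm_category("CELL", "Set"),
    toy_ddlm_category("CHEMICAL", "Set"),
    if (with_database) toy_ddlm_category("DATABASE", "Set"),
    toy_ddlm_category("AUDIT", "Set"),
    toy_ddlm_category("SYMMETRY_EQUIV", "Loop",
                      keys = "_symmetry_equiv.pos_site_id"),
    toy_ddlm_category("ATOM_SITE", "Loop", keys = "_atom_site.label"),
    toy_ddlm_category("ATOM_SITE_ANISO", "Loop",
                      keys = "_atom_site_aniso.label"),
    toy_ddlm_category("ATOM_TYPE", "Loop", keys = "_atom_type.symbol"),
    toy_ddlm_category("GEOM_BOND", "Loop",
                      keys = c("_geom_bond.atom_site_label_1",
                               "_geom_bond.atom_site_label_2",
                               "_geom_bond.site_symmetry_1",
                               "_geom_bond.site_symmetry_2")),
    toy_ddlm_frame("_cell.length_a", "cell", "length_a", "Real",
                   "Measurand", aliases = "_cell_length_a",
                   extra = "_enumeration.range 0.0:"),
    toy_ddlm_frame("_cell.length_a_su", "cell", "length_a_su", "Real",
                   "SU", aliases = "_cell_length_a_su",
                   extra = "_name.linked_item_id '_cell.length_a'"),
    toy_ddlm_frame("_cell.volume", "cell", "volume", "Real", "Number",
                   aliases = "_cell_volume",
                   extra = "_enumeration.range 0.0:"),
    toy_ddlm_frame("_cell.formula_units_z", "cell", "formula_units_z",
                   "Integer", "Number", aliases = "_cell_formula_units_z",
                   extra = "_enumeration.range 1:"),
    toy_ddlm_frame("_cell.setting", "cell", "setting", "Code", "State",
                   aliases = c("_cell_setting", "_symmetry_cell_setting"),
                   extra = c("loop_", "_enumeration_set.state",
                             "    triclinic monoclinic orthorhombic")),
    toy_ddlm_frame("_cell.metric_tensor", "cell", "metric_tensor", "Real",
                   "Number", container = "Matrix",
                   aliases = "_cell_metric_tensor"),
    toy_ddlm_frame("_chemical.formula_weight", "chemical",
                   "formula_weight", "Real", "Number",
                   aliases = "_chemical_formula_weight",
                   extra = "_enumeration.range 1.0:"),
    toy_ddlm_frame("_chemical.formula_weight_meas", "chemical",
                   "formula_weight_meas", "Real", "Number",
                   aliases = "_chemical_formula_weight_meas",
                   extra = "_definition_replaced.by '_chemical.formula_weight'"),
    toy_ddlm_frame("_chemical.melting_point", "chemical", "melting_point",
                   "Real", "Number", aliases = "_chemical_melting_point",
                   extra = "_enumeration.range 0.0:"),
    if (with_database)
      toy_ddlm_frame("_database.cod_code", "database", "cod_code", "Code",
                     "Encode", aliases = "_cod_database_code"),
    toy_ddlm_frame("_audit.creation_date", "audit", "creation_date",
                   "Date", "Encode", aliases = "_audit_creation_date"),
    toy_ddlm_frame("_symmetry_equiv.pos_as_xyz", "symmetry_equiv",
                   "pos_as_xyz", "Symop", "Encode",
                   aliases = "_symmetry_equiv_pos_as_xyz"),
    toy_ddlm_frame("_symmetry_equiv.pos_site_id", "symmetry_equiv",
                   "pos_site_id", "Index", "Number",
                   aliases = "_symmetry_equiv_pos_site_id",
                   extra = c("loop_", "_method.purpose",
                             "_method.expression", "    Evaluation",
                             "    'seq(packet)'")),
    toy_ddlm_frame("_atom_site.label", "atom_site", "label", "Code",
                   "Encode", aliases = "_atom_site_label"),
    toy_ddlm_frame("_atom_site.type_symbol", "atom_site", "type_symbol",
                   "Code", "Link", aliases = "_atom_site_type_symbol",
                   extra = "_name.linked_item_id '_atom_type.symbol'"),
    toy_ddlm_frame("_atom_site.occupancy", "atom_site", "occupancy",
                   "Real", "Measurand", aliases = "_atom_site_occupancy",
                   extra = "_enumeration.range 0.0:1.0"),
    toy_ddlm_frame("_atom_site.refinement_flags", "atom_site",
                   "refinement_flags", "Code", "State",
                   aliases = "_atom_site_refinement_flags",
                   extra = c("loop_", "_enumeration_set.state",
                             "    S G R D T U P '.'")),
    toy_ddlm_frame("_atom_site_aniso.label", "atom_site_aniso", "label",
                   "Code", "Link", aliases = "_atom_site_aniso_label",
                   extra = "_name.linked_item_id '_atom_site.label'"),
    toy_ddlm_frame("_atom_site_aniso.u_11", "atom_site_aniso", "u_11",
                   "Real", "Measurand", aliases = "_atom_site_aniso_u_11"),
    toy_ddlm_frame("_atom_type.symbol", "atom_type", "symbol", "Code",
                   "Encode", aliases = "_atom_type_symbol"),
    toy_ddlm_frame("_atom_type.scat_versus_stol_list", "atom_type",
                   "scat_versus_stol_list", "Real", "Number",
                   container = "List",
                   aliases = "_atom_type_scat_versus_stol_list"),
    toy_ddlm_frame("_geom_bond.atom_site_label_1", "geom_bond",
                   "atom_site_label_1", "Code", "Link",
                   aliases = "_geom_bond_atom_site_label_1",
                   extra = "_name.linked_item_id '_atom_site.label'"),
    toy_ddlm_frame("_geom_bond.atom_site_label_2", "geom_bond",
                   "atom_site_label_2", "Code", "Link",
                   aliases = "_geom_bond_atom_site_label_2",
                   extra = "_name.linked_item_id '_atom_site.label'"),
    toy_ddlm_frame("_geom_bond.site_symmetry_1", "geom_bond",
                   "site_symmetry_1", "Code", "Encode",
                   aliases = "_geom_bond_site_symmetry_1"),
    toy_ddlm_frame("_geom_bond.site_symmetry_2", "geom_bond",
                   "site_symmetry_2", "Code", "Encode",
                   aliases = "_geom_bond_site_symmetry_2"),
    toy_ddlm_frame("_geom_bond.distance", "geom_bond", "distance", "Real",
                   "Measurand", aliases = "_geom_bond_distance",
                   extra = "_enumeration.range 0.0:"))
}

toy_ddlm_text <- function() {
  c("#\\#CIF_2.0",
    "data_TOY_DIC",
    "    _dictionary.title TOY_DIC",
    "    _dictionary.class Instance",
    "    _dictionary.version 1.0",
    "    _dictionary.date 2021-02-14",
    "",
    toy_ddlm_body())
}

toy_ddlm_import_main_text <- function() {
  c("#\\#CIF_2.0",
    "data_TOY_DIC_IMPORTING",
    "    _dictionary.title TOY_DIC_IMPORTING",
    "    _dictionary.class Instance",
    "    _dictionary.version 1.0",
    "    _dictionary.date 2021-02-14",
    "",
    toy_ddlm_body(with_database = FALSE, import_head = TRUE))
}

toy_ddlm_import_ext_text <- function() {
  c("#\\#CIF_2.0",
    "data_TOY_EXT",
    "    _dictionary.title TOY_EXT",
    "    _dictionary.class Instance",
    "    _dictionary.version 1.0",
    "    _dictionary.date 2021-02-14",
    "",
    toy_ddlm_category("DATABASE", "Set"),
    toy_ddlm_frame("_database.cod_code", "database", "cod_code", "Code",
                   "Encode", aliases = "_cod_database_code"))
}

toy_reference_text <- function() {
  c("#\\#CIF_2.0",
    "data_TOY_DDL",
    "    _dictionary.title TOY_DDL",
    "    _dictionary.class Reference",
    "    _dictionary.version 1.0",
    "    _dictionary.date 2021-02-14",
    "    loop_",
    "    _dictionary_valid.scope",
    "    _dictionary_valid.option",
    "    _dictionary_valid.attributes",
    "    Dictionary Mandatory ['_dictionary.title' '_dictionary.class' '_dictionary.version' '_dictionary.date']",
    "    Dictionary Prohibited ['_definition.id']",
    "    Item Mandatory ['_definition.id' '_name.category_id' '_name.object_id']",
    "    Item Prohibited ['_dictionary.title']",
    "    Item Recommended ['_description.text']",
    "    Category Mandatory ['_definition.id' '_definition.class']")
}

#' Generate the mirrored toy dictionary pair
#'
#' A DDL1 and a DDLm dictionary covering every validated constraint:
#' Set-class singleton categories, Loop categories with simple and
#' composite keys, a parent/child sparse category pair, a measurand with a
#' separate s.u. item, aliases (including one absent from the DDL1
#' dictionary), a deprecated item, a concatenated-set item with states
#' (S, G, R, D, T, U, P, .), List and Matrix containers, and a dREL-method
#' stub on the symmetry id item. Also returns an import-split DDLm variant
#' and the toy reference dictionary holding application-scope rules. The
#' dictionaries are fixed study conditions and do not vary with the seed.
#'
#' @param seed Unused; kept so fixture interfaces are uniform.
#' @return List of character vectors: `ddl1_text`, `ddlm_text`,
#'   `reference_text`, `ddlm_import_main_text`, `ddlm_import_ext_text`.
#' @export
make_toy_dictionaries <- function(seed = 1L) {
  list(ddl1_text = toy_ddl1_text(),
       ddlm_text = toy_ddlm_text(),
       reference_text = toy_reference_text(),
       ddlm_import_main_text = toy_ddlm_import_main_text(),
       ddlm_import_ext_text = toy_ddlm_import_ext_text())
}

#' Parse and load the toy dictionaries
#'
#' @param toy Output of [make_toy_dictionaries()].
#' @return List with loaded `ddl1`, `ddlm`, the parsed `ddlm_doc` (for
#'   scope checking) and `reference_doc`.
#' @export
load_toy_dictionaries <- function(toy = make_toy_dictionaries()) {
  ddlm_doc <- parse_cif(toy$ddlm_text, file = "toy_ddlm.dic")
  list(ddl1 = load_ddl1(parse_cif(toy$ddl1_text, file = "toy_ddl1.dic")),
       ddlm = load_ddlm(ddlm_doc),
       ddlm_doc = ddlm_doc,
       reference_doc = parse_cif(toy$reference_text, file = "toy_ddl.dic"))
}

# ---- valid data file -----------------------------------------------------

vv <- function(text, quote = "none") cif_value(text, quote_style = quote)
vlist <- function(texts) cif_value(variant = "list",
                                   elements = lapply(texts, vv))

#' Generate a valid CIF fixture
#'
#' Builds a CIF 2.0 data block exercising every category of the toy
#' dictionaries that yields zero messages under both the DDL1 and the DDLm
#' suite with default options (all measurands carry a concise s.u.). The
#' same seed always yields identical text.
#'
#' @param seed Integer seed controlling sizes and values.
#' @return A fixture manifest: list with `doc` (the document structure),
#'   `cif_text`, `ddl_version` ("both"), `options`, `expected` (empty) and
#'   `seed`.
#' @export
make_valid_cif <- function(seed = 1L) {
  with_seed(seed, {
    n <- sample(3:6, 1)
    pool <- c("C", "N", "O", "S", "Fe", "Zn")
    els <- sample(pool, n, replace = TRUE)
    idx <- stats::ave(seq_along(els), els, FUN = seq_along)
    labels <- paste0(els, idx)
    types <- unique(els)
    k <- sample(2:4, 1)
    symops <- c("x,y,z", "-x,-y,-z", "-x+1/2,y+1/2,-z",
                "x+1/2,-y+1/2,z")[seq_len(k)]
    na <- min(2L, n)
    nb <- n - 1L
    block <- cif_block("toy_entry")
    block <- block_set_item(block, "_cod_database_code",
                            vv(sprintf("%07d", sample(1e6:5e6, 1))))
    block <- block_set_item(block, "_audit_creation_date",
                            vv(sprintf("20%02d-%02d-%02d", sample(15:24, 1),
                                       sample(1:12, 1), sample(1:28, 1))))
    block <- block_set_item(block, "_cell_length_a",
                            vv(sprintf("%.3f(%d)", stats::runif(1, 5, 25),
                                       sample(1:9, 1))))
    block <- block_set_item(block, "_cell_volume",
                            vv(sprintf("%.1f", stats::runif(1, 400, 2000))))
    block <- block_set_item(block, "_cell_formula_units_z",
                            vv(as.character(sample(1:8, 1))))
    block <- block_set_item(block, "_cell_setting",
                            vv(sample(c("triclinic", "monoclinic",
                                        "orthorhombic"), 1)))
    diagv <- sprintf("%.2f", stats::runif(3, 25, 650))
    block <- block_set_item(block, "_cell_metric_tensor", cif_value(
      variant = "list", elements = list(
        vlist(c(diagv[1], "0.0", "0.0")),
        vlist(c("0.0", diagv[2], "0.0")),
        vlist(c("0.0", "0.0", diagv[3])))))
    block <- block_set_item(block, "_chemical_formula_weight",
                            vv(sprintf("%.2f", stats::runif(1, 100, 600))))
    block <- block_set_item(block, "_chemical_melting_point",
                            vv(sprintf("%.2f", stats::runif(1, 250, 500))))
    block$loops <- list(
      cif_loop(c("_symmetry_equiv_pos_site_id",
                 "_symmetry_equiv_pos_as_xyz"),
               lapply(seq_len(k), function(i)
                 list(vv(as.character(i)), vv(symops[[i]])))),
      cif_loop(c("_atom_site_label", "_atom_site_type_symbol",
                 "_atom_site_occupancy", "_atom_site_refinement_flags"),
               lapply(seq_len(n), function(i)
                 list(vv(labels[[i]]), vv(els[[i]]),
                      vv(sprintf("%.2f(%d)", stats::runif(1, 0.5, 0.97),
                                 sample(1:5, 1))),
                      vv(sample(c("S", "D", "U", "P", "PDU", "DU"), 1))))),
      cif_loop(c("_atom_site_aniso_label", "_atom_site_aniso_u_11"),
               lapply(seq_len(na), function(i)
                 list(vv(labels[[i]]),
                      vv(sprintf("%.3f(%d)", stats::runif(1, 0.01, 0.08),
                                 sample(1:9, 1)))))),
      cif_loop(c("_atom_type_symbol", "_atom_type_scat_versus_stol_list"),
               lapply(types, function(t)
                 list(vv(t), vlist(sprintf("%.2f",
                                           stats::runif(3, 0, 2)))))),
      cif_loop(c("_geom_bond_atom_site_label_1",
                 "_geom_bond_atom_site_label_2",
                 "_geom_bond_site_symmetry_1", "_geom_bond_site_symmetry_2",
                 "_geom_bond_distance"),
               lapply(seq_len(nb), function(i)
                 list(vv(labels[[i]]), vv(labels[[i + 1L]]), vv("1_555"),
                      vv(sprintf("%d_555", i)),
                      vv(sprintf("%.2f(%d)", stats::runif(1, 1.2, 2.6),
                                 sample(1:9, 1)))))))
    doc <- cif_document(list(block), dialect = "cif20", file = "fixture.cif")
    list(doc = doc, cif_text = serialize_cif(doc), ddl_version = "both",
         mode = "data", options = cif_validation_options(),
         expected = list(), seed = seed)
  })
}

# ---- violation catalog ---------------------------------------------------

exp_msg <- function(code, subjects = character(), severity = "WARNING",
                    kind = NA_character_) {
  list(code = code, subjects = subjects, severity = severity, kind = kind)
}

exp_signature <- function(e) {
  paste(e$severity, e$code, if (is.na(e$kind)) "" else e$kind,
        paste(sort(e$subjects), collapse = ","), sep = "|")
}

# document-editing helpers used by injections (one block assumed)
ed_block <- function(doc) doc$blocks[[1]]
ed_set_block <- function(doc, b) { doc$blocks[[1]] <- b; doc }
ed_set_item <- function(doc, name, value) {
  ed_set_block(doc, block_set_item(ed_block(doc), name, value))
}
ed_remove_item <- function(doc, name) {
  b <- ed_block(doc)
  b$items[[tolower(name)]] <- NULL
  ed_set_block(doc, b)
}
ed_item_text <- function(doc, name) block_get_item(ed_block(doc), name)$text
ed_loop_index <- function(doc, name) find_loop_of(ed_block(doc), name)
ed_map_cell <- function(doc, name, row, f) {
  b <- ed_block(doc)
  i <- find_loop_of(b, name)
  j <- match(tolower(name), b$loops[[i]]$names)
  b$loops[[i]]$packets[[row]][[j]] <- f(b$loops[[i]]$packets[[row]][[j]])
  ed_set_block(doc, b)
}
ed_get_cell <- function(doc, name, row) {
  b <- ed_block(doc)
  i <- find_loop_of(b, name)
  j <- match(tolower(name), b$loops[[i]]$names)
  b$loops[[i]]$packets[[row]][[j]]
}
ed_remove_column <- function(doc, name) {
  b <- ed_block(doc)
  i <- find_loop_of(b, name)
  j <- match(tolower(name), b$loops[[i]]$names)
  lp <- b$loops[[i]]
  lp$names <- lp$names[-j]
  lp$orig_names <- lp$orig_names[-j]
  lp$packets <- lapply(lp$packets, function(p) p[-j])
  b$loops[[i]] <- lp
  ed_set_block(doc, b)
}
ed_remove_loop <- function(doc, name) {
  b <- ed_block(doc)
  b$loops[[find_loop_of(b, name)]] <- NULL
  ed_set_block(doc, b)
}
ed_add_column <- function(doc, loop_member, name, values) {
  b <- ed_block(doc)
  i <- find_loop_of(b, loop_member)
  lp <- b$loops[[i]]
  lp$names <- c(lp$names, tolower(name))
  lp$orig_names <- c(lp$orig_names, name)
  lp$packets <- lapply(seq_along(lp$packets), function(r)
    c(lp$packets[[r]], list(values[[r]])))
  b$loops[[i]] <- lp
  ed_set_block(doc, b)
}
append_su <- function(v) vv(paste0(v$text, "(3)"))
strip_su <- function(v) vv(sub("\\([0-9]+\\)$", "", v$text))

#' The violation catalog
#'
#' One entry per semantic message code. Each entry knows the dictionary
#' suite(s) it is validated under, the options it needs, the minimal edit
#' it applies to the valid fixture, and the exact messages the validator
#' must then emit under each suite (side-effect messages included).
#'
#' @return Named list of catalog entries.
#' @export
violation_catalog <- function() {
  gb1 <- "_geom_bond_atom_site_label_1"
  gb2 <- "_geom_bond_atom_site_label_2"
  list(
    value_outside_range = list(
      ddl_version = "ddl1", targets = "occupancy",
      edit = function(doc) ed_map_cell(doc, "_atom_site_occupancy", 1L,
                                       function(v) vv("1.50(2)")),
      expected = function(doc) list(
        ddl1 = list(exp_msg("value_outside_range", "_atom_site_occupancy")),
        ddlm = list(exp_msg("value_outside_range", "_atom_site_occupancy")),
        common = list())),
    value_outside_enum = list(
      ddl_version = "ddl1", targets = "setting",
      edit = function(doc) ed_set_item(doc, "_cell_setting",
                                       vv("Monoclinic")),
      expected = function(doc) list(
        ddl1 = list(exp_msg("value_outside_enum", "_cell_setting")),
        ddlm = list(), common = list())),
    extra_su = list(
      ddl_version = "ddl1", targets = "volume",
      edit = function(doc) ed_set_item(doc, "_cell_volume",
                                       append_su(block_get_item(
                                         ed_block(doc), "_cell_volume"))),
      expected = function(doc) list(
        ddl1 = list(exp_msg("extra_su", "_cell_volume")),
        ddlm = list(exp_msg("prohibited_su", "_cell_volume")),
        common = list())),
    missing_foreign_key_item = list(
      ddl_version = "both", targets = "atom_type",
      edit = function(doc) ed_remove_loop(doc, "_atom_type_symbol"),
      expected = function(doc) list(
        ddl1 = list(exp_msg("missing_foreign_key_item",
                            c("_atom_site_type_symbol",
                              "_atom_type_symbol"))),
        ddlm = list(exp_msg("missing_foreign_key_item",
                            c("_atom_site_type_symbol",
                              "_atom_type.symbol"))),
        common = list())),
    missing_foreign_key_value = list(
      ddl_version = "both", targets = "geom_bond",
      edit = function(doc) ed_map_cell(doc, gb1, 1L, function(v) vv("Q9")),
      expected = function(doc) list(
        ddl1 = list(exp_msg("missing_foreign_key_value",
                            c(gb1, "_atom_site_label"))),
        ddlm = list(exp_msg("missing_foreign_key_value",
                            c(gb1, "_atom_site.label"))),
        common = list())),
    nonunique_simple_key = list(
      ddl_version = "ddl1", targets = "symmetry",
      edit = function(doc) {
        first <- ed_get_cell(doc, "_symmetry_equiv_pos_as_xyz", 1L)
        ed_map_cell(doc, "_symmetry_equiv_pos_as_xyz", 2L,
                    function(v) vv(first$text))
      },
      expected = function(doc) list(
        ddl1 = list(exp_msg("nonunique_simple_key",
                            "_symmetry_equiv_pos_as_xyz")),
        ddlm = list(), common = list())),
    nonunique_composite_key = list(
      ddl_version = "ddl1", targets = "geom_bond",
      edit = function(doc) {
        l1 <- ed_get_cell(doc, gb1, 1L)
        l2 <- ed_get_cell(doc, gb2, 1L)
        doc <- ed_map_cell(doc, gb1, 2L, function(v) vv(l1$text))
        ed_map_cell(doc, gb2, 2L, function(v) vv(l2$text))
      },
      expected = function(doc) list(
        ddl1 = list(exp_msg("nonunique_composite_key", c(gb1, gb2))),
        ddlm = list(), common = list())),
    missing_key_item = list(
      ddl_version = "ddlm", targets = "geom_bond",
      edit = function(doc) ed_remove_column(doc,
                                            "_geom_bond_site_symmetry_2"),
      expected = function(doc) list(
        ddl1 = list(),
        ddlm = list(exp_msg("missing_key_item",
                            "_geom_bond.site_symmetry_2")),
        common = list())),
    missing_mandatory_loop_item = list(
      ddl_version = "ddl1", targets = "symmetry",
      edit = function(doc) ed_remove_column(doc,
                                            "_symmetry_equiv_pos_site_id"),
      expected = function(doc) list(
        ddl1 = list(exp_msg("missing_mandatory_loop_item",
                            "_symmetry_equiv_pos_site_id")),
        ddlm = list(), common = list())),
    mixed_category_loop = list(
      ddl_version = "ddl1", targets = c("symmetry", "setting"),
      edit = function(doc) {
        val <- ed_item_text(doc, "_cell_setting")
        doc <- ed_remove_item(doc, "_cell_setting")
        b <- ed_block(doc)
        nrow <- length(b$loops[[ed_loop_index(doc,
          "_symmetry_equiv_pos_as_xyz")]]$packets)
        ed_add_column(doc, "_symmetry_equiv_pos_as_xyz", "_cell_setting",
                      lapply(seq_len(nrow), function(i) vv(val)))
      },
      expected = function(doc) list(
        ddl1 = list(
          exp_msg("mixed_category_loop",
                  c("_symmetry_equiv_pos_site_id",
                    "_symmetry_equiv_pos_as_xyz", "_cell_setting")),
          exp_msg("unlooped_value_in_loop", "_cell_setting")),
        ddlm = list(exp_msg("unlooped_value_in_loop", "_cell_setting")),
        common = list())),
    compromised_category_integrity = list(
      ddl_version = "ddl1", targets = "geom_bond",
      edit = function(doc) {
        b <- ed_block(doc)
        i <- find_loop_of(b, "_geom_bond_distance")
        col <- loop_column(b$loops[[i]], "_geom_bond_distance")
        doc <- ed_remove_column(doc, "_geom_bond_distance")
        b <- ed_block(doc)
        b$loops[[length(b$loops) + 1L]] <-
          cif_loop("_geom_bond_distance", lapply(col, list))
        ed_set_block(doc, b)
      },
      expected = function(doc) list(
        ddl1 = list(
          exp_msg("compromised_category_integrity", c(gb1, gb2)),
          exp_msg("missing_key_item", gb1),
          exp_msg("missing_key_item", gb2)),
        ddlm = list(
          exp_msg("compromised_category_integrity", "geom_bond"),
          exp_msg("missing_key_item", "_geom_bond.atom_site_label_1"),
          exp_msg("missing_key_item", "_geom_bond.atom_site_label_2"),
          exp_msg("missing_key_item", "_geom_bond.site_symmetry_1"),
          exp_msg("missing_key_item", "_geom_bond.site_symmetry_2")),
        common = list())),
    unlooped_value_in_loop = list(
      ddl_version = "both", targets = c("length_a", "volume"),
      edit = function(doc) {
        la <- block_get_item(ed_block(doc), "_cell_length_a")
        vo <- block_get_item(ed_block(doc), "_cell_volume")
        doc <- ed_remove_item(doc, "_cell_length_a")
        doc <- ed_remove_item(doc, "_cell_volume")
        b <- ed_block(doc)
        b$loops[[length(b$loops) + 1L]] <-
          cif_loop(c("_cell_length_a", "_cell_volume"), list(list(la, vo)))
        ed_set_block(doc, b)
      },
      expected = function(doc) list(
        ddl1 = list(exp_msg("unlooped_value_in_loop", "_cell_length_a"),
                    exp_msg("unlooped_value_in_loop", "_cell_volume")),
        ddlm = list(exp_msg("unlooped_value_in_loop", "_cell_length_a"),
                    exp_msg("unlooped_value_in_loop", "_cell_volume")),
        common = list())),
    looped_value_outside_loop = list(
      ddl_version = "ddl1", targets = "symmetry",
      edit = function(doc) {
        doc <- ed_remove_loop(doc, "_symmetry_equiv_pos_as_xyz")
        ed_set_item(doc, "_symmetry_equiv_pos_as_xyz", vv("x,y,z"))
      },
      expected = function(doc) list(
        ddl1 = list(exp_msg("looped_value_outside_loop",
                            "_symmetry_equiv_pos_as_xyz")),
        ddlm = list(), common = list())),
    non_numeric_value = list(
      ddl_version = "ddl1", targets = "melting_point",
      edit = function(doc) ed_set_item(doc, "_chemical_melting_point",
                                       vv("24 C", quote = "single")),
      expected = function(doc) list(
        ddl1 = list(exp_msg("non_numeric_value", "_chemical_melting_point")),
        ddlm = list(exp_msg("type_violation", "_chemical_melting_point",
                            kind = "Real")),
        common = list())),
    type_violation = list(
      ddl_version = "ddlm", targets = "formula_units_z",
      edit = function(doc) ed_set_item(doc, "_cell_formula_units_z",
                                       vv("4.0")),
      expected = function(doc) list(
        ddl1 = list(),
        ddlm = list(exp_msg("type_violation", "_cell_formula_units_z",
                            kind = "Integer")),
        common = list())),
    forbidden_symbol = list(
      ddl_version = "ddlm", targets = "cod_code",
      edit = function(doc) ed_set_item(doc, "_cod_database_code",
                                       vv("12 34", quote = "single")),
      expected = function(doc) list(
        ddl1 = list(),
        ddlm = list(exp_msg("forbidden_symbol", "_cod_database_code",
                            kind = "Code")),
        common = list())),
    value_not_in_list = list(
      ddl_version = "ddlm", targets = "metric_tensor",
      edit = function(doc) ed_set_item(doc, "_cell_metric_tensor",
                                       vlist(c("1.0", "2.0", "3.0"))),
      expected = function(doc) list(
        ddl1 = list(),
        ddlm = list(exp_msg("value_not_in_list", "_cell_metric_tensor")),
        common = list())),
    missing_top_level_container = list(
      ddl_version = "ddlm", targets = "atom_type",
      edit = function(doc) ed_map_cell(
        doc, "_atom_type_scat_versus_stol_list", 1L,
        function(v) cif_value("0.1 1.2\n0.3 0.9",
                              quote_style = "multiline")),
      expected = function(doc) list(
        ddl1 = list(),
        ddlm = list(exp_msg("missing_top_level_container",
                            "_atom_type_scat_versus_stol_list")),
        common = list())),
    alias_value_mismatch = list(
      ddl_version = "ddlm", targets = c("setting", "setting_alias"),
      edit = function(doc) {
        cur <- ed_item_text(doc, "_cell_setting")
        other <- setdiff(c("triclinic", "monoclinic", "orthorhombic"),
                         cur)[[1]]
        ed_set_item(doc, "_symmetry_cell_setting", vv(other))
      },
      expected = function(doc) list(
        ddl1 = list(),
        ddlm = list(exp_msg("alias_value_mismatch",
                            c("_cell_setting", "_symmetry_cell_setting"))),
        common = list())),
    unrecognized_data_name = list(
      ddl_version = "both", targets = "new_tag",
      edit = function(doc) ed_set_item(doc, "_not_a_real_tag", vv("5")),
      expected = function(doc) list(
        ddl1 = list(), ddlm = list(),
        common = list(exp_msg("unrecognized_data_name", "_not_a_real_tag",
                              severity = "NOTE")))),
    missing_su = list(
      ddl_version = "ddlm", targets = "length_a",
      edit = function(doc) ed_set_item(doc, "_cell_length_a",
                                       strip_su(block_get_item(
                                         ed_block(doc), "_cell_length_a"))),
      expected = function(doc) list(
        ddl1 = list(),
        ddlm = list(exp_msg("missing_su", "_cell_length_a")),
        common = list())),
    prohibited_su = list(
      ddl_version = "ddlm", targets = "volume",
      edit = function(doc) ed_set_item(doc, "_cell_volume",
                                       append_su(block_get_item(
                                         ed_block(doc), "_cell_volume"))),
      expected = function(doc) list(
        ddl1 = list(exp_msg("extra_su", "_cell_volume")),
        ddlm = list(exp_msg("prohibited_su", "_cell_volume")),
        common = list())),
    mismatching_su = list(
      ddl_version = "ddlm", targets = "length_a",
      edit = function(doc) ed_set_item(doc, "_cell_length_a_su", vv("0.9")),
      expected = function(doc) list(
        ddl1 = list(),
        ddlm = list(exp_msg("mismatching_su",
                            c("_cell_length_a", "_cell.length_a_su"))),
        common = list())),
    deprecated_item = list(
      ddl_version = "ddlm", targets = "formula_weight_meas",
      options = cif_validation_options(report_deprecated = TRUE),
      edit = function(doc) ed_set_item(doc, "_chemical_formula_weight_meas",
                                       vv("240.3")),
      expected = function(doc) list(
        ddl1 = list(exp_msg("deprecated_item",
                            c("_chemical_formula_weight_meas",
                              "_chemical_formula_weight"),
                            severity = "NOTE")),
        ddlm = list(exp_msg("deprecated_item",
                            c("_chemical_formula_weight_meas",
                              "_chemical.formula_weight"),
                            severity = "NOTE")),
        common = list())),
    scope_violation = list(
      ddl_version = "ddlm", targets = "dictionary", mode = "dictionary",
      edit = function(doc) NULL,  # operates on the dictionary text instead
      expected = function(doc) list(
        ddl1 = list(), ddlm = list(),
        common = list(exp_msg("scope_violation", "_dictionary.date"))))
  )
}

#' Names of all generatable violation codes
#'
#' @return Character vector (one entry per semantic taxonomy code).
#' @export
violation_codes <- function() names(violation_catalog())

#' Inject violations into a valid fixture
#'
#' Applies each catalog entry's minimal edit to the valid fixture and
#' appends exactly the messages a correct validator must emit. Entries
#' touching the same part of the fixture conflict and cannot be combined.
#'
#' @param manifest Output of [make_valid_cif()].
#' @param codes Character vector of catalog entry names.
#' @param ddl_version Suite(s) the fixture is to be validated under;
#'   defaults to the single entry's declared suite, or "both" for
#'   combinations.
#' @return The modified manifest with `cif_text`, `expected`, `options`
#'   and `ddl_version` updated.
#' @export
inject_violations <- function(manifest, codes, ddl_version = NULL) {
  catalog <- violation_catalog()
  stopifnot(all(codes %in% names(catalog)))
  entries <- catalog[codes]
  targets <- unlist(lapply(entries, function(e) e$targets))
  if (anyDuplicated(targets))
    stop("conflicting injections: shared target '",
         targets[duplicated(targets)][1], "'")
  if (any(vapply(entries, function(e) identical(e$mode, "dictionary"),
                 logical(1))) && length(entries) > 1L)
    stop("dictionary-scope injections cannot be combined with data-file ones")
  if (is.null(ddl_version))
    ddl_version <- if (length(entries) == 1L) entries[[1]]$ddl_version
                   else "both"
  doc <- manifest$doc
  opts <- manifest$options
  expected <- manifest$expected
  mode <- "data"
  for (nm in names(entries)) {
    e <- entries[[nm]]
    if (identical(e$mode, "dictionary")) {
      mode <- "dictionary"
      txt <- toy_ddlm_text()
      manifest$cif_text <- txt[!grepl("_dictionary.date", txt,
                                      fixed = TRUE)]
    } else {
      doc <- e$edit(doc)
    }
    if (!is.null(e$options)) {
      opts$report_deprecated <- opts$report_deprecated ||
        e$options$report_deprecated
      opts$ignore_missing_su <- opts$ignore_missing_su ||
        e$options$ignore_missing_su
    }
    slots <- e$expected(doc)
    expected <- c(expected, slots$common)
    if (ddl_version %in% c("ddl1", "both")) expected <- c(expected,
                                                          slots$ddl1)
    if (ddl_version %in% c("ddlm", "both")) expected <- c(expected,
                                                          slots$ddlm)
  }
  if (mode == "data") {
    manifest$doc <- doc
    manifest$cif_text <- serialize_cif(doc)
  }
  manifest$mode <- mode
  manifest$options <- opts
  manifest$expected <- expected
  manifest$ddl_version <- ddl_version
  manifest
}

#' Run the validator on a fixture manifest
#'
#' Parses the manifest text from scratch and validates it under the
#' suite(s) the manifest declares (or, for dictionary-mode manifests,
#' runs the application-scope check against the toy reference dictionary).
#'
#' @param manifest A fixture manifest.
#' @param dicts Output of [load_toy_dictionaries()].
#' @return Sorted list of `cif_message`.
#' @export
validate_manifest <- function(manifest, dicts = load_toy_dictionaries()) {
  doc <- parse_cif(manifest$cif_text, file = "fixture.cif")
  if (identical(manifest$mode, "dictionary"))
    return(validate_ddlm_dictionary(doc, dicts$reference_doc))
  ddl1 <- if (manifest$ddl_version %in% c("ddl1", "both")) dicts$ddl1
  ddlm <- if (manifest$ddl_version %in% c("ddlm", "both")) dicts$ddlm
  validate_document(doc, ddl1, ddlm, manifest$options)
}

#' Expected-message multiset of a manifest (positions elided)
#'
#' @param manifest A fixture manifest.
#' @return Sorted character vector comparable with [message_multiset()].
#' @export
manifest_expected_multiset <- function(manifest) {
  if (length(manifest$expected) == 0L) return(character())
  sort(vapply(manifest$expected, exp_signature, character(1)))
}
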