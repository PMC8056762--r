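#' @title DDL1 validation checks
#' @description The DDL1 constraint validators: data type, s.u.
#'   eligibility, enumeration sets, permitted ranges, looped-list
#'   eligibility, loop keys, loop integrity and category homogeneity,
#'   referential integrity, deprecation, mandatory loop items and declared
#'   uniqueness sets, plus unrecognized-name detection. Special values
#'   (`?`, `.`) are exempt from value-level checks and from foreign-key
#'   matching. All comparisons are case-sensitive: DDL1 character strings
#'   are strictly case sensitive.
#' @name ddl1_checks
NULL

#' Validation options
#'
#' @param report_deprecated Report usage of deprecated (replaced) items.
#' @param ignore_missing_su Suppress missing-s.u. findings (DDLm).
#' @param treat_as_set Data names whose enumerated values are validated as
#'   concatenations of set members; replaces the default set (the classic
#'   refinement-flags item).
#' @return A list of class "cif_validation_options".
#' @export
cif_validation_options <- function(report_deprecated = FALSE,
                                   ignore_missing_su = FALSE,
                                   treat_as_set = "_atom_site_refinement_flags") {
  structure(list(report_deprecated = report_deprecated,
                 ignore_missing_su = ignore_missing_su,
                 treat_as_set = tolower(treat_as_set)),
            class = "cif_validation_options")
}

block_path_of <- function(block) {
  if (block$kind == "global") "global_" else paste0("data_", block$name)
}

msg_maker <- function(block, file, suite = NA_character_) {
  bp <- block_path_of(block)
  function(code, detail, severity = "WARNING", line = NA_integer_,
           subjects = character(), kind = NA_character_) {
    cif_message(code, severity, detail, file = file, line = line,
                block = bp, subjects = subjects, type_kind = kind,
                suite = suite)
  }
}

value_raw <- function(v) if (v$variant %in% c("string", "special")) v$text else NA_character_

# enumeration membership under DDL1 rules: case-sensitive strings, numeric
# comparison for numb-typed enumerations
d1_enum_member <- function(raw, enum, type) {
  if (type == "numb") {
    n <- parse_measured_number(raw)
    if (!is.null(n)) {
      en <- suppressWarnings(vapply(enum, function(e) {
        p <- parse_measured_number(e)
        if (is.null(p)) NA_real_ else p$value
      }, numeric(1)))
      if (any(!is.na(en) & en == n$value)) return(TRUE)
    }
  }
  raw %in% enum
}

#' DDL1 value checks: type, s.u. eligibility, enumeration, range
#'
#' @param block A `cif_block`.
#' @param dict A `ddl1_dictionary`.
#' @param opts See [cif_validation_options()].
#' @param file File label for messages.
#' @return List of `cif_message`.
#' @export
d1_check_values <- function(block, dict, opts = cif_validation_options(),
                            file = "-") {
  mk <- msg_maker(block, file, suite = "ddl1")
  out <- list()
  for (name in unique(block_data_names(block))) {
    def <- lookup_ddl1(dict, name)
    if (is.null(def)) next
    for (occ in occurrences_of(block, name)) {
      v <- occ$value
      if (!(v$variant %in% c("string", "special"))) next
      if (is_special_value(v)) next
      raw <- v$text
      num <- parse_measured_number(raw)
      if (def$type == "numb") {
        if (is.null(num)) {
          out <- c(out, list(mk("non_numeric_value", sprintf(
            "value '%s' of %s is not numeric", raw, name),
            line = occ$line, subjects = name)))
          next
        }
        if (!is.na(num$su) && !def$su_eligible)
          out <- c(out, list(mk("extra_su", sprintf(
            "value '%s' of %s carries a standard uncertainty although the item is not s.u.-eligible",
            raw, name), line = occ$line, subjects = name)))
      }
      if (!is.null(def$enumeration)) {
        if (tolower(name) %in% opts$treat_as_set) {
          tk <- tokenize_concatenated(raw, def$enumeration)
          if (!tk$ok)
            out <- c(out, list(mk("value_outside_enum", sprintf(
              "value '%s' of %s cannot be decomposed into enumeration set members (offset %d)",
              raw, name, tk$offset), line = occ$line, subjects = name)))
        } else if (!d1_enum_member(raw, def$enumeration, def$type)) {
          out <- c(out, list(mk("value_outside_enum", sprintf(
            "value '%s' of %s is outside the enumeration set", raw, name),
            line = occ$line, subjects = name)))
        }
      }
      rng <- def$enumeration_range
      if (!is.null(rng) && !rng$character && !is.null(num)) {
        if ((!is.na(rng$lower) && num$value < rng$lower) ||
            (!is.na(rng$upper) && num$value > rng$upper))
          out <- c(out, list(mk("value_outside_range", sprintf(
            "value '%s' of %s is outside the permitted range %s:%s", raw,
            name, ifelse(is.na(rng$lower), "", rng$lower),
            ifelse(is.na(rng$upper), "", rng$upper)),
            line = occ$line, subjects = name)))
      }
    }
  }
  out
}

#' DDL1 looped-list eligibility
#'
#' Items with list state `yes` must appear only in loops; state `no` bars
#' them from loops; `both` allows either context.
#'
#' @inheritParams d1_check_values
#' @return List of `cif_message`.
#' @export
d1_check_loop_membership <- function(block, dict,
                                     opts = cif_validation_options(),
                                     file = "-") {
  mk <- msg_maker(block, file, suite = "ddl1")
  out <- list()
  for (name in names(block$items)) {
    def <- lookup_ddl1(dict, name)
    if (!is.null(def) && identical(def$list_state, "yes"))
      out <- c(out, list(mk("looped_value_outside_loop", sprintf(
        "%s must appear in a looped list but is given as a single value",
        name), line = block$items[[name]]$line, subjects = name)))
  }
  for (lp in block$loops) {
    for (name in lp$names) {
      def <- lookup_ddl1(dict, name)
      if (!is.null(def) && identical(def$list_state, "no"))
        out <- c(out, list(mk("unlooped_value_in_loop", sprintf(
          "%s must not appear in a looped list", name),
          line = lp$line, subjects = name)))
    }
  }
  out
}

loop_key_tuples <- function(lp, key_names) {
  idx <- match(key_names, lp$names)
  vapply(lp$packets, function(p)
    paste(vapply(idx, function(i) {
      r <- value_raw(p[[i]])
      if (is.na(r)) "" else r
    }, character(1)), collapse = "\r"), character(1))
}

duplicate_tuple_messages <- function(mk, lp, key_names, tuples, code_single,
                                     code_multi, what) {
  out <- list()
  dup <- unique(tuples[duplicated(tuples)])
  for (d in dup) {
    shown <- gsub("\r", ", ", d)
    code <- if (length(key_names) == 1L) code_single else code_multi
    out <- c(out, list(mk(code, sprintf(
      "duplicate %s value (%s) for (%s) in a looped list", what, shown,
      paste(key_names, collapse = ", ")),
      line = lp$line, subjects = key_names)))
  }
  out
}

#' DDL1 looped-list key checks
#'
#' Items of a loop reference group (`_list_reference`) must all be present
#' in the loop; uniqueness of the combined key value is checked only when
#' the key is complete (partial composite keys are skipped, as the legacy
#' semantics require).
#'
#' @inheritParams d1_check_values
#' @return List of `cif_message`.
#' @export
d1_check_loop_keys <- function(block, dict, opts = cif_validation_options(),
                               file = "-") {
  mk <- msg_maker(block, file, suite = "ddl1")
  out <- list()
  for (lp in block$loops) {
    groups <- list()
    for (name in lp$names) {
      def <- lookup_ddl1(dict, name)
      if (!is.null(def) && !is.null(def$list_reference))
        groups[[paste(sort(def$list_reference), collapse = "\r")]] <-
          def$list_reference
    }
    for (group in groups) {
      missing <- setdiff(group, lp$names)
      if (length(missing) > 0L) {
        for (m in missing)
          out <- c(out, list(mk("missing_key_item", sprintf(
            "looped list lacks the key item %s", m),
            line = lp$line, subjects = m)))
        next  # uniqueness is not checked on a partial key
      }
      tuples <- loop_key_tuples(lp, group)
      out <- c(out, duplicate_tuple_messages(
        mk, lp, group, tuples, "nonunique_simple_key",
        "nonunique_composite_key", "key"))
    }
  }
  out
}

#' DDL1 loop integrity and category homogeneity
#'
#' Items sharing one loop reference must reside in a single loop; a loop
#' must hold items of a single category.
#'
#' @inheritParams d1_check_values
#' @return List of `cif_message`.
#' @export
d1_check_loop_integrity <- function(block, dict,
                                    opts = cif_validation_options(),
                                    file = "-") {
  mk <- msg_maker(block, file, suite = "ddl1")
  out <- list()
  ref_loops <- list()
  for (i in seq_along(block$loops)) {
    lp <- block$loops[[i]]
    cats <- character()
    for (name in lp$names) {
      def <- lookup_ddl1(dict, name)
      if (is.null(def)) next
      if (!is.na(def$category)) cats <- c(cats, def$category)
      if (!is.null(def$list_reference)) {
        key <- paste(sort(def$list_reference), collapse = "\r")
        ref_loops[[key]] <- unique(c(ref_loops[[key]], i))
      }
    }
    if (length(unique(cats)) > 1L)
      out <- c(out, list(mk("mixed_category_loop", sprintf(
        "looped list mixes items from several categories (%s)",
        paste(sort(unique(cats)), collapse = ", ")),
        line = lp$line, subjects = lp$names)))
  }
  for (key in names(ref_loops)) {
    if (length(ref_loops[[key]]) > 1L)
      out <- c(out, list(mk("compromised_category_integrity", sprintf(
        "items sharing the loop reference (%s) are split across %d looped lists",
        gsub("\r", ", ", key), length(ref_loops[[key]])),
        subjects = strsplit(key, "\r", fixed = TRUE)[[1]])))
  }
  out
}

#' DDL1 referential integrity
#'
#' Parent items must be present and contain every (non-special) child
#' value; parent values need not be unique. Matching is case-sensitive.
#'
#' @inheritParams d1_check_values
#' @return List of `cif_message`.
#' @export
d1_check_referential_integrity <- function(block, dict,
                                           opts = cif_validation_options(),
                                           file = "-") {
  mk <- msg_maker(block, file, suite = "ddl1")
  out <- list()
  present <- unique(block_data_names(block))
  for (child in names(dict$parent_of)) {
    if (!(child %in% present)) next
    parent <- dict$parent_of[[child]]
    if (!(parent %in% present)) {
      out <- c(out, list(mk("missing_foreign_key_item", sprintf(
        "%s references %s, which is not given", child, parent),
        subjects = c(child, parent))))
      next
    }
    parent_vals <- vapply(
      Filter(function(v) !is_special_value(v) &&
               v$variant %in% c("string", "special"),
             values_of(block, parent)),
      function(v) v$text, character(1))
    for (occ in occurrences_of(block, child)) {
      v <- occ$value
      if (!(v$variant %in% c("string", "special"))) next
      if (is_special_value(v)) next
      if (!(v$text %in% parent_vals))
        out <- c(out, list(mk("missing_foreign_key_value", sprintf(
          "value '%s' of %s is absent from the parent item %s", v$text,
          child, parent), line = occ$line, subjects = c(child, parent))))
    }
  }
  out
}

#' DDL1 deprecation check (disabled unless requested)
#'
#' @inheritParams d1_check_values
#' @return List of `cif_message` (NOTE severity).
#' @export
d1_check_deprecation <- function(block, dict,
                                 opts = cif_validation_options(),
                                 file = "-") {
  if (!opts$report_deprecated) return(list())
  mk <- msg_maker(block, file, suite = "ddl1")
  out <- list()
  present <- unique(block_data_names(block))
  for (name in present) {
    rep <- dict$replaced_by[[name]]
    if (is.null(rep)) next
    detail <- if (rep %in% present)
      sprintf(
        "%s is deprecated and replaced by %s; simultaneous presence of both may lead to contradictory data",
        name, rep)
    else sprintf("%s is deprecated; use %s instead", name, rep)
    out <- c(out, list(mk("deprecated_item", detail, severity = "NOTE",
                          subjects = c(name, rep))))
  }
  out
}

#' DDL1 mandatory loop items and declared uniqueness sets
#'
#' @inheritParams d1_check_values
#' @return List of `cif_message`.
#' @export
d1_check_mandatory_and_uniqueness <- function(block, dict,
                                              opts = cif_validation_options(),
                                              file = "-") {
  mk <- msg_maker(block, file, suite = "ddl1")
  out <- list()
  mandatory_defs <- unique(Filter(function(d) isTRUE(d$list_mandatory),
                                  dict$defs))
  for (lp in block$loops) {
    cats <- unique(stats::na.omit(vapply(lp$names, function(n) {
      d <- lookup_ddl1(dict, n)
      if (is.null(d)) NA_character_ else d$category
    }, character(1))))
    for (md in mandatory_defs) {
      if (!is.na(md$category) && md$category %in% cats &&
          !any(md$names %in% lp$names))
        out <- c(out, list(mk("missing_mandatory_loop_item", sprintf(
          "looped list of category %s lacks the mandatory item %s",
          md$category, md$names[[1]]),
          line = lp$line, subjects = md$names[[1]])))
    }
    seen_groups <- character()
    for (name in lp$names) {
      def <- lookup_ddl1(dict, name)
      if (is.null(def) || is.null(def$list_uniqueness)) next
      group <- def$list_uniqueness
      gkey <- paste(sort(group), collapse = "\r")
      if (gkey %in% seen_groups) next
      seen_groups <- c(seen_groups, gkey)
      if (!all(group %in% lp$names)) next
      tuples <- loop_key_tuples(lp, group)
      out <- c(out, duplicate_tuple_messages(
        mk, lp, group, tuples, "nonunique_composite_key",
        "nonunique_composite_key", "uniqueness-set"))
    }
  }
  out
}

#' Unrecognized data names
#'
#' A data name absent from every supplied dictionary (DDL1 defs, DDLm defs
#' and aliases alike) is reported as a NOTE.
#'
#' @param block A `cif_block`.
#' @param dicts List of loaded dictionaries (`ddl1_dictionary` and/or
#'   `ddlm_dictionary`).
#' @param file File label for messages.
#' @return List of `cif_message`.
#' @export
check_unrecognized <- function(block, dicts, file = "-") {
  if (inherits(dicts, c("ddl1_dictionary", "ddlm_dictionary")))
    dicts <- list(dicts)
  mk <- msg_maker(block, file)
  out <- list()
  for (name in unique(block_data_names(block))) {
    known <- any(vapply(dicts, function(d) {
      if (inherits(d, "ddl1_dictionary")) !is.null(lookup_ddl1(d, name))
      else !is.null(lookup_ddlm(d, name))
    }, logical(1)))
    if (!known)
      out <- c(out, list(mk("unrecognized_data_name", sprintf(
        "data name %s is not defined in any supplied dictionary", name),
        severity = "NOTE", subjects = name)))
  }
  out
}

#' Run the full DDL1 suite on one block
#'
#' @inheritParams d1_check_values
#' @return List of `cif_message` (unsorted).
#' @export
validate_block_ddl1 <- function(block, dict,
                                opts = cif_validation_options(),
                                file = "-") {
  c(d1_check_values(block, dict, opts, file),
    d1_check_loop_membership(block, dict, opts, file),
    d1_check_loop_keys(block, dict, opts, file),
    d1_check_loop_integrity(block, dict, opts, file),
    d1_check_referential_integrity(block, dict, opts, file),
    d1_check_deprecation(block, dict, opts, file),
    d1_check_mandatory_and_uniqueness(block, dict, opts, file))
}
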