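#' @title DDLm validation checks
#' @description The DDLm constraint validators: content types, containers,
#'   standard-uncertainty presence/prohibition/mismatch, type-aware
#'   enumeration sets and ranges, category loop classes, category
#'   integrity with the sparse child-category exception, category keys
#'   (with defaults and dREL-method suppression), referential integrity
#'   with normalized matching, aliasing, deprecation and dictionary
#'   application scope.
#' @name ddlm_checks
NULL

numeric_contents <- function(contents) {
  contents %in% c("Integer", "Real", "Count", "Index")
}

# separate-su value paired with one occurrence of a measurand; su_names are
# all the names (canonical id and aliases) the s.u. item may appear under
paired_su_value <- function(block, occ, su_names) {
  if (is.null(su_names)) return(NULL)
  for (su_name in su_names) {
    if (occ$looped) {
      lp <- block$loops[[occ$loop_index]]
      col <- loop_column(lp, su_name)
      if (!is.null(col)) {
        idx <- which(vapply(lp$packets, function(p)
          any(vapply(p, identical, logical(1), y = occ$value)), logical(1)))
        if (length(idx) >= 1L) return(col[[idx[[1]]]])
      }
    }
    v <- block_get_item(block, su_name)
    if (!is.null(v)) return(v)
  }
  NULL
}

#' DDLm value checks
#'
#' Content-type conformance, enumeration sets and ranges (type-aware,
#' normalized comparison), and the three standard-uncertainty findings:
#' a measurand without an s.u. in either notation (`missing_su`,
#' suppressed by `ignore_missing_su`), a concise s.u. on a non-measurand
#' (`prohibited_su`), and disagreeing concise and separate-item s.u.
#' values (`mismatching_su`). Data names listed in `treat_as_set` are
#' validated as concatenations of enumeration set members.
#'
#' @param block A `cif_block`.
#' @param dict A `ddlm_dictionary`.
#' @param opts See [cif_validation_options()].
#' @param file File label for messages.
#' @return List of `cif_message`.
#' @export
m_check_values <- function(block, dict, opts = cif_validation_options(),
                           file = "-") {
  mk <- msg_maker(block, file, suite = "ddlm")
  out <- list()
  for (name in unique(block_data_names(block))) {
    def <- lookup_ddlm(dict, name)
    if (is.null(def)) next
    su_id <- dict$su_of[[def$id]]
    su_names <- if (is.null(su_id)) NULL else {
      sd <- lookup_ddlm(dict, su_id)
      if (is.null(sd)) su_id else unique(c(sd$id, sd$aliases))
    }
    for (occ in occurrences_of(block, name)) {
      v <- occ$value
      if (!(v$variant %in% c("string", "special"))) next
      if (is_special_value(v)) next
      if (def$container != "Single") next  # handled by the container check
      raw <- v$text
      chk <- check_content_type(raw, def$contents)
      if (!chk$ok) {
        code <- chk$violation
        out <- c(out, list(mk(code, sprintf(
          "value '%s' of %s violates the %s content type", raw, name,
          chk$kind), line = occ$line, subjects = name, kind = chk$kind)))
        next
      }
      if (numeric_contents(def$contents)) {
        num <- parse_measured_number(raw)
        concise <- !is.na(num$su)
        sep_v <- paired_su_value(block, occ, su_names)
        sep_num <- if (!is.null(sep_v) && sep_v$variant == "string")
          parse_measured_number(sep_v$text) else NULL
        if (identical(def$purpose, "Measurand")) {
          if (concise && !is.null(sep_num)) {
            if (!isTRUE(all.equal(num$su, sep_num$value)))
              out <- c(out, list(mk("mismatching_su", sprintf(
                "s.u. of %s differs between the concise notation ('%s') and the separate item %s ('%s')",
                name, raw, su_id, sep_v$text),
                line = occ$line, subjects = c(name, su_id))))
          } else if (!concise && is.null(sep_num) &&
                     !opts$ignore_missing_su) {
            out <- c(out, list(mk("missing_su", sprintf(
              "measurand %s lacks a standard uncertainty", name),
              line = occ$line, subjects = name)))
          }
        } else if (concise && !identical(def$purpose, "SU")) {
          out <- c(out, list(mk("prohibited_su", sprintf(
            "value '%s' of %s carries a standard uncertainty although the item is not a measurand",
            raw, name), line = occ$line, subjects = name)))
        }
      }
      if (!is.null(def$enum_states)) {
        if (tolower(name) %in% opts$treat_as_set) {
          tk <- tokenize_concatenated(raw, def$enum_states)
          if (!tk$ok)
            out <- c(out, list(mk("value_outside_enum", sprintf(
              "value '%s' of %s cannot be decomposed into enumeration set members (offset %d)",
              raw, name, tk$offset), line = occ$line, subjects = name)))
        } else {
          nstates <- vapply(def$enum_states, normalize_value, character(1),
                            type = def$contents)
          if (!(normalize_value(raw, def$contents) %in% nstates))
            out <- c(out, list(mk("value_outside_enum", sprintf(
              "value '%s' of %s is outside the enumeration set", raw, name),
              line = occ$line, subjects = name)))
        }
      }
      rng <- def$enum_range
      if (!is.null(rng) && !rng$character) {
        num <- parse_measured_number(raw)
        if (!is.null(num) &&
            ((!is.na(rng$lower) && num$value < rng$lower) ||
             (!is.na(rng$upper) && num$value > rng$upper)))
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

#' DDLm container checks
#'
#' A non-Single container requires a compound value at the top level
#' (`missing_top_level_container`); a Matrix requires every element to be
#' a row list (`value_not_in_list` when a bare scalar appears where a list
#' is required); a Single container bars compound values.
#'
#' @inheritParams m_check_values
#' @return List of `cif_message`.
#' @export
m_check_container <- function(block, dict, opts = cif_validation_options(),
                              file = "-") {
  mk <- msg_maker(block, file, suite = "ddlm")
  out <- list()
  for (name in unique(block_data_names(block))) {
    def <- lookup_ddlm(dict, name)
    if (is.null(def)) next
    for (occ in occurrences_of(block, name)) {
      v <- occ$value
      if (v$variant == "special" || is_special_value(v)) next
      cont <- def$container
      if (cont == "Single") {
        if (v$variant %in% c("list", "table"))
          out <- c(out, list(mk("missing_top_level_container", sprintf(
            "%s must be a single value but is stored as a %s", name,
            v$variant), line = occ$line, subjects = name)))
      } else if (cont %in% c("List", "Matrix", "Array")) {
        if (v$variant != "list") {
          out <- c(out, list(mk("missing_top_level_container", sprintf(
            "%s must be stored in a %s container but is given as a plain value",
            name, cont), line = occ$line, subjects = name)))
        } else if (cont == "Matrix") {
          bad <- which(vapply(v$elements, function(e) e$variant != "list",
                              logical(1)))
          if (length(bad) > 0L)
            out <- c(out, list(mk("value_not_in_list", sprintf(
              "element %d of the %s matrix is a bare value where a row list is required",
              bad[[1]], name), line = occ$line, subjects = name)))
        }
      } else if (cont == "Table" && v$variant != "table") {
        out <- c(out, list(mk("missing_top_level_container", sprintf(
          "%s must be stored in a Table container but is given as a plain value",
          name), line = occ$line, subjects = name)))
      }
    }
  }
  out
}

#' DDLm looped-list eligibility via category class
#'
#' Items of a Set-class category must not appear in a looped list; items
#' of a Loop-class category may appear anywhere (a single unlooped value
#' reads as a one-packet loop).
#'
#' @inheritParams m_check_values
#' @return List of `cif_message`.
#' @export
m_check_loop_class <- function(block, dict, opts = cif_validation_options(),
                               file = "-") {
  mk <- msg_maker(block, file, suite = "ddlm")
  out <- list()
  for (lp in block$loops) {
    for (name in lp$names) {
      cat_ <- category_of(dict, name)
      if (!is.null(cat_) && identical(cat_$class, "Set"))
        out <- c(out, list(mk("unlooped_value_in_loop", sprintf(
          "%s belongs to the Set-class category %s and must not appear in a looped list",
          name, cat_$id), line = lp$line, subjects = name)))
    }
  }
  out
}

loop_categories <- function(dict, lp, collapse_children = FALSE) {
  cats <- character()
  for (name in lp$names) {
    d <- lookup_ddlm(dict, name)
    if (is.null(d) || is.na(d$category_id)) next
    cid <- d$category_id
    if (collapse_children && !is.null(dict$child_of[[cid]]))
      cid <- dict$child_of[[cid]]
    cats <- c(cats, cid)
  }
  unique(cats)
}

#' DDLm category integrity and homogeneity
#'
#' Items of one looped category must reside in one loop; a loop may mix
#' two categories only when one is the declared sparse child of the other
#' (e.g. anisotropic displacement items inside the main atom-site loop).
#'
#' @inheritParams m_check_values
#' @return List of `cif_message`.
#' @export
m_check_category_integrity <- function(block, dict,
                                       opts = cif_validation_options(),
                                       file = "-") {
  mk <- msg_maker(block, file, suite = "ddlm")
  out <- list()
  cat_loops <- list()
  for (i in seq_along(block$loops)) {
    lp <- block$loops[[i]]
    for (cid in loop_categories(dict, lp))
      cat_loops[[cid]] <- unique(c(cat_loops[[cid]], i))
    eff <- loop_categories(dict, lp, collapse_children = TRUE)
    eff <- eff[vapply(eff, function(cid)
      !identical(dict$categories[[cid]]$class, "Set"), logical(1))]
    if (length(eff) > 1L)
      out <- c(out, list(mk("mixed_category_loop", sprintf(
        "looped list mixes items from several categories (%s)",
        paste(sort(eff), collapse = ", ")),
        line = lp$line, subjects = lp$names)))
  }
  for (cid in names(cat_loops)) {
    cat_ <- dict$categories[[cid]]
    if (is.null(cat_) || !identical(cat_$class, "Loop")) next
    if (length(cat_loops[[cid]]) > 1L)
      out <- c(out, list(mk("compromised_category_integrity", sprintf(
        "items of category %s are split across %d looped lists", cid,
        length(cat_loops[[cid]])), subjects = cid)))
  }
  out
}

#' DDLm category key checks
#'
#' Every declared key item must be present in the category's loop unless a
#' default value or a dREL evaluation method can supply it (a missing key
#' item with a method is silently ignored; one whose linked parent item is
#' present in the same loop is derivable and also silent). Uniqueness is
#' always evaluated over the present key items (normalized values), even
#' for a partial key.
#'
#' @inheritParams m_check_values
#' @return List of `cif_message`.
#' @export
m_check_category_keys <- function(block, dict,
                                  opts = cif_validation_options(),
                                  file = "-") {
  mk <- msg_maker(block, file, suite = "ddlm")
  out <- list()
  for (lp in block$loops) {
    for (cid in loop_categories(dict, lp)) {
      cat_ <- dict$categories[[cid]]
      if (is.null(cat_) || !identical(cat_$class, "Loop")) next
      key <- cat_$key_items
      if (length(key) == 0L) next
      # loops usually carry legacy alias names while keys are declared with
      # canonical ids: resolve membership alias-transparently
      col_ids <- vapply(lp$names, function(n) {
        d <- lookup_ddlm(dict, n)
        if (is.null(d)) NA_character_ else d$id
      }, character(1))
      key_cols <- vapply(key, function(k) {
        kd <- lookup_ddlm(dict, k)
        if (is.null(kd)) return(NA_integer_)
        hit <- which(col_ids == kd$id)
        if (length(hit)) hit[[1]] else NA_integer_
      }, integer(1))
      for (j in which(is.na(key_cols))) {
        k <- key[[j]]
        kd <- lookup_ddlm(dict, k)
        if (is.null(kd)) next
        if (kd$has_method) next
        if (!is.na(kd$default)) next
        if (!is.na(kd$linked_item_id)) {
          ld <- lookup_ddlm(dict, kd$linked_item_id)
          if (!is.null(ld) && any(col_ids == ld$id, na.rm = TRUE))
            next  # derivable from the linked parent item in the same loop
        }
        out <- c(out, list(mk("missing_key_item", sprintf(
          "looped list of category %s lacks the key item %s", cid, k),
          line = lp$line, subjects = k)))
      }
      present <- key[!is.na(key_cols)]
      idx <- key_cols[!is.na(key_cols)]
      if (length(present) >= 1L) {
        types <- vapply(present, function(k) {
          kd <- lookup_ddlm(dict, k)
          if (is.null(kd)) "Text" else kd$contents
        }, character(1))
        tuples <- vapply(lp$packets, function(p)
          paste(vapply(seq_along(idx), function(j) {
            r <- value_raw(p[[idx[[j]]]])
            if (is.na(r)) "" else normalize_value(r, types[[j]])
          }, character(1)), collapse = "\r"), character(1))
        out <- c(out, duplicate_tuple_messages(
          mk, lp, present, tuples, "nonunique_simple_key",
          "nonunique_composite_key", "normalized key"))
      }
    }
  }
  out
}

#' DDLm referential integrity
#'
#' Linked items (foreign keys declared on the referencing side) must have
#' their parent item present, and every non-special child value must have
#' a normalized match among the parent values. S.u. links are excluded
#' (they are covered by the s.u. checks).
#'
#' @inheritParams m_check_values
#' @return List of `cif_message`.
#' @export
m_check_referential_integrity <- function(block, dict,
                                          opts = cif_validation_options(),
                                          file = "-") {
  mk <- msg_maker(block, file, suite = "ddlm")
  out <- list()
  present <- unique(block_data_names(block))
  seen <- character()
  for (name in present) {
    def <- lookup_ddlm(dict, name)
    if (is.null(def) || def$id %in% seen) next
    seen <- c(seen, def$id)
    if (is.na(def$linked_item_id) || identical(def$purpose, "SU")) next
    parent <- def$linked_item_id
    pd <- lookup_ddlm(dict, parent)
    ptype <- if (is.null(pd)) "Text" else pd$contents
    parent_present <- parent %in% present ||
      (!is.null(pd) && any(c(pd$id, pd$aliases) %in% present))
    if (!parent_present) {
      out <- c(out, list(mk("missing_foreign_key_item", sprintf(
        "%s references %s, which is not given", name, parent),
        subjects = c(name, parent))))
      next
    }
    parent_names <- if (is.null(pd)) parent else unique(c(pd$id, pd$aliases))
    parent_vals <- vapply(
      Filter(function(v) v$variant == "string" && !is_special_value(v),
             unlist(lapply(parent_names, values_of, block = block),
                    recursive = FALSE)),
      function(v) normalize_value(v$text, ptype), character(1))
    for (occ in occurrences_of(block, name)) {
      v <- occ$value
      if (!(v$variant %in% c("string", "special"))) next
      if (is_special_value(v)) next
      if (!(normalize_value(v$text, ptype) %in% parent_vals))
        out <- c(out, list(mk("missing_foreign_key_value", sprintf(
          "value '%s' of %s is absent from the parent item %s", v$text,
          name, parent), line = occ$line, subjects = c(name, parent))))
    }
  }
  out
}

#' DDLm alias agreement
#'
#' When several names of one definition occur as unlooped items their
#' normalized values must agree. Looped aliased values are not validated;
#' such definitions are skipped and recorded in the `skipped_aliases`
#' attribute of the result.
#'
#' @inheritParams m_check_values
#' @return List of `cif_message`, with attribute `skipped_aliases`.
#' @export
m_check_aliases <- function(block, dict, opts = cif_validation_options(),
                            file = "-") {
  mk <- msg_maker(block, file, suite = "ddlm")
  out <- list()
  skipped <- character()
  present <- unique(block_data_names(block))
  looped_names <- unique(unlist(lapply(block$loops, function(l) l$names)))
  by_def <- split(present, vapply(present, function(n) {
    d <- lookup_ddlm(dict, n)
    if (is.null(d)) paste0("?", n) else d$id
  }, character(1)))
  for (id in names(by_def)) {
    names_ <- by_def[[id]]
    if (startsWith(id, "?") || length(names_) < 2L) next
    if (any(names_ %in% looped_names)) {
      skipped <- c(skipped, id)
      next
    }
    def <- lookup_ddlm(dict, id)
    vals <- vapply(names_, function(n) {
      v <- block_get_item(block, n)
      if (is.null(v) || v$variant != "string") NA_character_
      else normalize_value(v$text, def$contents)
    }, character(1))
    vals <- vals[!is.na(vals)]
    if (length(unique(vals)) > 1L)
      out <- c(out, list(mk("alias_value_mismatch", sprintf(
        "aliased data items %s carry differing values",
        paste(sort(names_), collapse = ", ")),
        subjects = sort(names_))))
  }
  attr(out, "skipped_aliases") <- skipped
  out
}

#' DDLm deprecation check (disabled unless requested)
#'
#' @inheritParams m_check_values
#' @return List of `cif_message` (NOTE severity).
#' @export
m_check_deprecation <- function(block, dict,
                                opts = cif_validation_options(),
                                file = "-") {
  if (!opts$report_deprecated) return(list())
  mk <- msg_maker(block, file, suite = "ddlm")
  out <- list()
  seen <- character()
  for (name in unique(block_data_names(block))) {
    def <- lookup_ddlm(dict, name)
    if (is.null(def) || def$id %in% seen) next
    seen <- c(seen, def$id)
    if (!is.na(def$replaced_by))
      out <- c(out, list(mk("deprecated_item", sprintf(
        "%s is deprecated; use %s instead", name, def$replaced_by),
        severity = "NOTE", subjects = c(name, def$replaced_by))))
  }
  out
}

#' Dictionary application-scope check
#'
#' Only run when the file under validation is itself a DDLm dictionary.
#' The reference dictionary's validity rules (scope x option x attribute
#' list) determine which attributes are mandatory, recommended or
#' prohibited in each context: the top data block is the Dictionary
#' context and every save frame the context given by its declared
#' definition scope. Mandatory-absent and prohibited-present findings are
#' WARNINGs; recommended-absent is a NOTE.
#'
#' @param dict_doc `cif_document` of the dictionary being validated.
#' @param reference_doc `cif_document` of the reference dictionary holding
#'   the validity rules.
#' @param file File label for messages.
#' @return List of `cif_message`.
#' @export
m_check_application_scope <- function(dict_doc, reference_doc, file = "-") {
  rules <- scope_rules_of(reference_doc)
  if (length(rules) == 0L || length(dict_doc$blocks) == 0L) return(list())
  out <- list()
  blk <- dict_doc$blocks[[1]]
  contexts <- list(list(scope = "Dictionary",
                        path = paste0("data_", blk$name),
                        names = unique(block_data_names(blk))))
  walk <- function(frames, prefix) {
    for (fr in frames) {
      sc <- item_text(fr, "_definition.scope")
      if (is.na(sc)) sc <- "Item"
      contexts[[length(contexts) + 1L]] <<-
        list(scope = sc, path = paste0(prefix, "/save_", fr$name),
             names = unique(block_data_names(fr)))
      walk(fr$frames, paste0(prefix, "/save_", fr$name))
    }
  }
  walk(blk$frames, paste0("data_", blk$name))
  for (ctx in contexts) {
    for (rule in rules) {
      if (!identical(tolower(rule$scope), tolower(ctx$scope))) next
      opt <- tolower(rule$option)
      if (opt == "mandatory") {
        for (a in setdiff(rule$attributes, ctx$names))
          out <- c(out, list(cif_message("scope_violation", "WARNING",
            sprintf("mandatory attribute %s is absent from the %s context",
                    a, ctx$scope), file = file, block = ctx$path,
            subjects = a)))
      } else if (opt == "prohibited") {
        for (a in intersect(rule$attributes, ctx$names))
          out <- c(out, list(cif_message("scope_violation", "WARNING",
            sprintf("attribute %s is prohibited in the %s context", a,
                    ctx$scope), file = file, block = ctx$path,
            subjects = a)))
      } else if (opt == "recommended") {
        for (a in setdiff(rule$attributes, ctx$names))
          out <- c(out, list(cif_message("scope_violation", "NOTE",
            sprintf("recommended attribute %s is absent from the %s context",
                    a, ctx$scope), file = file, block = ctx$path,
            subjects = a)))
      }
    }
  }
  out
}

scope_rules_of <- function(reference_doc) {
  if (length(reference_doc$blocks) == 0L) return(list())
  blk <- reference_doc$blocks[[1]]
  rules <- list()
  for (lp in blk$loops) {
    if (!all(c("_dictionary_valid.scope", "_dictionary_valid.option",
               "_dictionary_valid.attributes") %in% lp$names)) next
    for (p in lp$packets) {
      scope <- p[[match("_dictionary_valid.scope", lp$names)]]$text
      option <- p[[match("_dictionary_valid.option", lp$names)]]$text
      av <- p[[match("_dictionary_valid.attributes", lp$names)]]
      attrs <- if (av$variant == "list")
        vapply(av$elements, function(e) tolower(e$text), character(1))
      else tolower(av$text)
      rules[[length(rules) + 1L]] <- list(scope = scope, option = option,
                                          attributes = attrs)
    }
  }
  rules
}

#' Run the full DDLm suite on one block
#'
#' @inheritParams m_check_values
#' @return List of `cif_message` (unsorted), with attribute
#'   `skipped_aliases`.
#' @export
validate_block_ddlm <- function(block, dict,
                                opts = cif_validation_options(),
                                file = "-") {
  al <- m_check_aliases(block, dict, opts, file)
  out <- c(m_check_values(block, dict, opts, file),
           m_check_container(block, dict, opts, file),
           m_check_loop_class(block, dict, opts, file),
           m_check_category_integrity(block, dict, opts, file),
           m_check_category_keys(block, dict, opts, file),
           m_check_referential_integrity(block, dict, opts, file),
           al,
           m_check_deprecation(block, dict, opts, file))
  attr(out, "skipped_aliases") <- attr(al, "skipped_aliases")
  out
}
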