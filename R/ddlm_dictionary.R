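#' @title DDLm dictionaries
#' @description Loads DDLm dictionaries (CIF 2.0 files whose definitions
#'   live in save frames) with embedded-import resolution, alias tables, a
#'   category tree with classes and keys, and the standard-uncertainty link
#'   table derived from purpose=SU definitions.
#' @name ddlm_dictionary
NULL

#' Resolve embedded dictionary imports
#'
#' Scans every save frame for an `_import.get` attribute (a CIF 2.0 list of
#' tables with `file` and `save` entries) and merges the named frames from
#' the located documents into the top-level block. Duplicate frame codes
#' resolve local-wins; import modes finer than whole-frame merging degrade
#' to full with a warning; cycles are detected and fail.
#'
#' @param doc A `cif_document` (dictionary).
#' @param locator Function mapping an import file name to a parsed
#'   `cif_document`, or NULL when it cannot be supplied.
#' @param missing_policy "fail" or "warn" when the locator cannot supply an
#'   imported dictionary.
#' @param .stack Internal: import chain for cycle detection.
#' @return The merged `cif_document`; import warnings are appended to
#'   `$warnings`.
#' @export
resolve_imports <- function(doc, locator,
                            missing_policy = c("fail", "warn"),
                            .stack = character()) {
  missing_policy <- match.arg(missing_policy)
  if (length(doc$blocks) == 0L) return(doc)
  blk <- doc$blocks[[1]]
  warn <- function(detail) {
    doc$warnings[[length(doc$warnings) + 1L]] <<-
      cif_message("dictionary_warning", "WARNING", detail, file = doc$file)
  }
  frame_codes <- function(b) tolower(vapply(b$frames, function(f) f$name,
                                            character(1)))
  collect_imports <- function(frames) {
    out <- list()
    for (fr in frames) {
      v <- block_get_item(fr, "_import.get")
      if (!is.null(v) && v$variant == "list") {
        for (entry in v$elements) {
          if (entry$variant != "table") next
          get_ent <- function(k) {
            e <- entry$entries[[k]]
            if (is.null(e)) NA_character_ else e$text
          }
          out[[length(out) + 1L]] <- list(file = get_ent("file"),
                                          save = get_ent("save"),
                                          mode = get_ent("mode"))
        }
      }
      out <- c(out, collect_imports(fr$frames))
    }
    out
  }
  for (imp in collect_imports(blk$frames)) {
    if (is.na(imp$file)) next
    if (imp$file %in% .stack)
      stop(sprintf("import cycle detected: %s",
                   paste(c(.stack, imp$file), collapse = " -> ")))
    if (!is.na(imp$mode) && tolower(imp$mode) != "full")
      warn(sprintf("import mode '%s' not supported; treated as Full",
                   imp$mode))
    target <- locator(imp$file)
    if (is.null(target)) {
      if (missing_policy == "fail")
        stop(sprintf("imported dictionary '%s' cannot be located", imp$file))
      warn(sprintf("imported dictionary '%s' cannot be located; skipped",
                   imp$file))
      next
    }
    target <- resolve_imports(target, locator, missing_policy,
                              .stack = c(.stack, imp$file))
    if (length(target$blocks) == 0L) next
    tframes <- target$blocks[[1]]$frames
    wanted <- if (is.na(imp$save)) tframes else
      Filter(function(f) tolower(f$name) == tolower(imp$save), tframes)
    if (!is.na(imp$save) && length(wanted) == 0L) {
      if (missing_policy == "fail")
        stop(sprintf("frame '%s' not found in imported dictionary '%s'",
                     imp$save, imp$file))
      warn(sprintf("frame '%s' not found in imported dictionary '%s'",
                   imp$save, imp$file))
    }
    for (fr in wanted) {
      if (tolower(fr$name) %in% frame_codes(blk)) next  # local wins
      blk$frames[[length(blk$frames) + 1L]] <- fr
    }
  }
  doc$blocks[[1]] <- blk
  doc
}

#' A search-path locator for imports
#'
#' @param paths Directories searched, in order, for the imported file name.
#' @return A function suitable as `locator` in [resolve_imports()].
#' @export
import_path_locator <- function(paths) {
  function(name) {
    for (p in paths) {
      f <- file.path(p, name)
      if (file.exists(f)) return(read_cif(f))
    }
    NULL
  }
}

ddlm_frame_attrs <- function(fr) {
  aliases <- tolower(item_texts(fr, "_alias.definition_id"))
  key_names <- tolower(item_texts(fr, "_category_key.name"))
  key_id <- tolower(item_text(fr, "_category.key_id"))
  if (length(key_names) == 0L && !is.na(key_id)) key_names <- key_id
  range <- parse_ddl1_range(item_text(fr, "_enumeration.range"))
  list(
    id = tolower(item_text(fr, "_definition.id")),
    scope = {
      s <- item_text(fr, "_definition.scope")
      if (is.na(s)) "Item" else s
    },
    class = {
      cl <- item_text(fr, "_definition.class")
      if (is.na(cl)) "Datum" else cl
    },
    category_id = tolower(item_text(fr, "_name.category_id")),
    object_id = tolower(item_text(fr, "_name.object_id")),
    contents = {
      ct <- item_text(fr, "_type.contents")
      if (is.na(ct)) "Text" else ct
    },
    container = {
      co <- item_text(fr, "_type.container")
      if (is.na(co)) "Single" else co
    },
    purpose = {
      p <- item_text(fr, "_type.purpose")
      if (is.na(p)) "Describe" else p
    },
    enum_states = {
      st <- item_texts(fr, "_enumeration_set.state")
      if (length(st)) st else NULL
    },
    enum_range = range,
    default = item_text(fr, "_enumeration.default"),
    linked_item_id = tolower(item_text(fr, "_name.linked_item_id")),
    replaced_by = tolower(item_text(fr, "_definition_replaced.by")),
    aliases = aliases,
    key_items = key_names,
    has_method = "_method.expression" %in% block_data_names(fr))
}

#' Load a DDLm dictionary
#'
#' Every Item frame is indexed under its canonical id and all of its
#' aliases (aliasing is symmetric: no name has precedence). Category frames
#' build the category tree with classes (Set/Loop) and keys. The
#' measurand -> s.u.-item table is inverted from purpose=SU definitions'
#' `_name.linked_item_id`. A Loop category whose key items all link into
#' another Loop category is recorded as that category's child (the
#' sparse-table exception used by e.g. anisotropic displacement loops).
#'
#' @param doc A `cif_document` (imports already resolved if any).
#' @return A list of class "ddlm_dictionary": `defs` (name/alias -> def),
#'   `categories`, `su_of`, `child_of`, `warnings`.
#' @export
load_ddlm <- function(doc) {
  if (!inherits(doc, "cif_document")) {
    docs <- doc
    stopifnot(length(docs) >= 1L)
    doc <- docs[[1]]
    for (d in docs[-1])
      if (length(d$blocks) > 0L)
        doc$blocks[[1]]$frames <- c(doc$blocks[[1]]$frames,
                                    d$blocks[[1]]$frames)
  }
  if (length(doc$blocks) == 0L) stop("empty dictionary document")
  blk <- doc$blocks[[1]]
  defs <- list()
  canonical <- list()
  categories <- list()
  warnings <- character()
  walk <- function(frames) {
    for (fr in frames) {
      at <- ddlm_frame_attrs(fr)
      if (!is.na(at$id)) {
        if (identical(at$scope, "Category") ||
            at$class %in% c("Set", "Loop", "Head")) {
          cid <- sub("^_", "", at$id)
          categories[[cid]] <<- list(
            id = cid, parent = at$category_id, class = at$class,
            key_items = at$key_items)
          if (at$class == "Loop" && length(at$key_items) == 0L)
            warnings <<- c(warnings, sprintf(
              "Loop category '%s' declares no key items", cid))
        } else {
          all_names <- unique(c(at$id, at$aliases))
          for (nm in all_names) {
            if (!is.null(canonical[[nm]]) &&
                !identical(canonical[[nm]], at$id))
              stop(sprintf(
                "name '%s' claimed by two definitions ('%s' and '%s')",
                nm, canonical[[nm]], at$id))
            canonical[[nm]] <<- at$id
            defs[[nm]] <<- at
          }
        }
      }
      walk(fr$frames)
    }
  }
  walk(blk$frames)
  su_of <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    if (identical(d$purpose, "SU") && !is.na(d$linked_item_id) &&
        nm == d$id)
      su_of[[d$linked_item_id]] <- d$id
  }
  # child categories: Loop category whose key items all link into one other
  # Loop category
  child_of <- list()
  for (cid in names(categories)) {
    cat_ <- categories[[cid]]
    if (!identical(cat_$class, "Loop") || length(cat_$key_items) == 0L) next
    targets <- character()
    ok <- TRUE
    for (k in cat_$key_items) {
      kd <- defs[[k]]
      if (is.null(kd) || is.na(kd$linked_item_id)) { ok <- FALSE; break }
      td <- defs[[kd$linked_item_id]]
      if (is.null(td)) { ok <- FALSE; break }
      targets <- c(targets, td$category_id)
    }
    if (ok && length(unique(targets)) == 1L && unique(targets) != cid &&
        identical(categories[[unique(targets)]]$class, "Loop"))
      child_of[[cid]] <- unique(targets)
  }
  structure(list(defs = defs, categories = categories, su_of = su_of,
                 child_of = child_of, warnings = warnings),
            class = "ddlm_dictionary")
}

#' Look up a DDLm definition, alias-transparently and case-insensitively
#'
#' @param dict A `ddlm_dictionary`.
#' @param name Data name or alias.
#' @return The definition list (same object for every alias), or NULL.
#' @export
lookup_ddlm <- function(dict, name) {
  dict$defs[[tolower(name)]]
}

#' Category of a data name
#'
#' @param dict A `ddlm_dictionary`.
#' @param name Data name or alias.
#' @return The category record, or NULL.
#' @export
category_of <- function(dict, name) {
  d <- lookup_ddlm(dict, name)
  if (is.null(d) || is.na(d$category_id)) return(NULL)
  dict$categories[[d$category_id]]
}

#' Declared key items of a category
#'
#' @param dict A `ddlm_dictionary`.
#' @param category Category id.
#' @return Character vector of data names (possibly empty).
#' @export
key_of <- function(dict, category) {
  cat_ <- dict$categories[[tolower(category)]]
  if (is.null(cat_)) character() else cat_$key_items
}

#' @export
print.ddlm_dictionary <- function(x, ...) {
  cat(sprintf(
    "<ddlm_dictionary> %d names/aliases, %d categories, %d su links\n",
    length(x$defs), length(x$categories), length(x$su_of)))
  invisible(x)
}
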