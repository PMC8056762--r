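#' @title DDL1 dictionaries
#' @description Loads legacy DDL1 dictionaries (CIF 1.1 files, one or more
#'   data blocks per definition) into a definition table keyed by data
#'   name, with the parent/child and replacement relations merged across
#'   definitions.
#' @name ddl1_dictionary
NULL

# text of a scalar item, or NA
item_text <- function(block, name) {
  v <- block_get_item(block, name)
  if (is.null(v) || v$variant != "string") NA_character_ else v$text
}

# all textual values of a name in a block (unlooped or looped)
item_texts <- function(block, name) {
  vals <- values_of(block, name)
  vals <- Filter(function(v) v$variant == "string", vals)
  vapply(vals, function(v) v$text, character(1))
}

parse_ddl1_range <- function(raw) {
  if (is.na(raw)) return(NULL)
  parts <- regmatches(raw, regexec("^([^:]*):([^:]*)$", raw))[[1]]
  if (length(parts) == 0L) return(NULL)
  lo_raw <- parts[2]
  hi_raw <- parts[3]
  lo <- if (nzchar(lo_raw)) parse_measured_number(lo_raw) else NA
  hi <- if (nzchar(hi_raw)) parse_measured_number(hi_raw) else NA
  is_char <- (nzchar(lo_raw) && is.null(lo)) || (nzchar(hi_raw) && is.null(hi))
  list(lower = if (nzchar(lo_raw) && !is.null(lo)) lo$value else NA_real_,
       upper = if (nzchar(hi_raw) && !is.null(hi)) hi$value else NA_real_,
       character = is_char)
}

ddl1_definition_from_block <- function(block) {
  names_ <- tolower(item_texts(block, "_name"))
  if (length(names_) == 0L) return(NULL)
  type <- item_text(block, "_type")
  if (is.na(type)) type <- "unset"
  conds <- tolower(item_texts(block, "_type_conditions"))
  enum <- item_texts(block, "_enumeration")
  range <- parse_ddl1_range(item_text(block, "_enumeration_range"))
  list_state <- tolower(item_text(block, "_list"))
  if (is.na(list_state)) list_state <- "unset"
  related_items <- item_texts(block, "_related_item")
  related_funcs <- tolower(item_texts(block, "_related_function"))
  related <- if (length(related_items))
    data.frame(func = related_funcs, target = tolower(related_items),
               stringsAsFactors = FALSE) else
    data.frame(func = character(), target = character(),
               stringsAsFactors = FALSE)
  replaced_by <- NA_character_
  if (any(related$func == "replace"))
    replaced_by <- related$target[related$func == "replace"][1]
  list(
    names = names_,
    category = tolower(item_text(block, "_category")),
    type = tolower(type),
    su_eligible = any(conds %in% c("esu", "su")),
    enumeration = if (length(enum)) enum else NULL,
    enumeration_range = range,
    list_state = list_state,
    list_reference = {
      r <- tolower(item_texts(block, "_list_reference"))
      if (length(r)) r else NULL
    },
    list_mandatory = identical(tolower(item_text(block, "_list_mandatory")),
                               "yes"),
    list_uniqueness = {
      u <- tolower(item_texts(block, "_list_uniqueness"))
      if (length(u)) u else NULL
    },
    links_parent = {
      p <- tolower(item_text(block, "_list_link_parent"))
      if (is.na(p)) NULL else p
    },
    links_children = {
      ch <- tolower(item_texts(block, "_list_link_child"))
      if (length(ch)) ch else NULL
    },
    related = related,
    replaced_by = replaced_by)
}

#' Load DDL1 dictionaries
#'
#' Each definition block may define several data names at once (looped
#' `_name`); all names share one definition. Parent/child referential
#' relations may be declared on the parent side (`_list_link_child`), the
#' child side (`_list_link_parent`) or both; declarations are merged with
#' the child side winning on conflict (with a warning). Cyclic parent
#' declarations are broken at the closing edge with a warning. When two
#' blocks (possibly from different files) define the same name, the first
#' definition wins and a warning is recorded.
#'
#' @param docs A `cif_document` or list of them (later documents extend,
#'   never silently override).
#' @return A list of class "ddl1_dictionary" with `defs` (name ->
#'   definition), `parent_of` (child -> parent name), `replaced_by` and
#'   `warnings` (character vector).
#' @export
load_ddl1 <- function(docs) {
  if (inherits(docs, "cif_document")) docs <- list(docs)
  defs <- list()
  warnings <- character()
  child_side <- list()   # child -> parent
  parent_side <- list()
  for (doc in docs) {
    for (block in doc$blocks) {
      if (block$kind != "data") next
      def <- ddl1_definition_from_block(block)
      if (is.null(def)) next
      for (nm in def$names) {
        if (!is.null(defs[[nm]])) {
          warnings <- c(warnings, sprintf(
            "data name '%s' defined more than once; first definition kept",
            nm))
          next
        }
        defs[[nm]] <- def
      }
      if (!is.null(def$links_parent))
        for (nm in def$names) child_side[[nm]] <- def$links_parent
      if (!is.null(def$links_children))
        for (ch in def$links_children) parent_side[[ch]] <- def$names[[1]]
      if (!is.null(def$enumeration_range) && def$enumeration_range$character)
        warnings <- c(warnings, sprintf(
          "character range declared for '%s'; only numeric ranges are checked",
          def$names[[1]]))
    }
  }
  parent_of <- parent_side
  for (ch in names(child_side)) {
    if (!is.null(parent_of[[ch]]) &&
        !identical(parent_of[[ch]], child_side[[ch]]))
      warnings <- c(warnings, sprintf(
        "conflicting parent declarations for '%s' ('%s' vs '%s'); child-side declaration kept",
        ch, parent_of[[ch]], child_side[[ch]]))
    parent_of[[ch]] <- child_side[[ch]]
  }
  # acyclicity: walk each chain; break the edge that closes a cycle
  for (start in names(parent_of)) {
    seen <- start
    cur <- start
    while (!is.null(parent_of[[cur]])) {
      nxt <- parent_of[[cur]]
      if (nxt %in% seen) {
        warnings <- c(warnings, sprintf(
          "cyclic parent declaration involving '%s'; edge '%s' -> '%s' dropped",
          start, cur, nxt))
        parent_of[[cur]] <- NULL
        break
      }
      seen <- c(seen, nxt)
      cur <- nxt
    }
  }
  replaced_by <- list()
  for (nm in names(defs)) {
    if (!is.na(defs[[nm]]$replaced_by))
      replaced_by[[nm]] <- defs[[nm]]$replaced_by
  }
  danglers <- character()
  referenced <- unique(c(unlist(parent_of), unlist(replaced_by),
                         unlist(lapply(defs, function(d) d$list_reference))))
  for (r in referenced) if (is.null(defs[[r]])) danglers <- c(danglers, r)
  structure(list(defs = defs, parent_of = parent_of,
                 replaced_by = replaced_by, danglers = danglers,
                 warnings = warnings),
            class = "ddl1_dictionary")
}

#' Look up a DDL1 definition (case-insensitive)
#'
#' @param dict A `ddl1_dictionary`.
#' @param name Data name.
#' @return The definition list, or NULL when absent.
#' @export
lookup_ddl1 <- function(dict, name) {
  dict$defs[[tolower(name)]]
}

#' @export
print.ddl1_dictionary <- function(x, ...) {
  cat(sprintf("<ddl1_dictionary> %d data names, %d parent links, %d warnings\n",
              length(x$defs), length(x$parent_of), length(x$warnings)))
  invisible(x)
}
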