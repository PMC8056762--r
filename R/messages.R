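#' @title Validation messages
#' @description Canonical validation-message records, the closed code
#'   taxonomy, deterministic rendering and ordering. Messages are designed
#'   for Unix-filter use: one line per finding, machine-parsable by a fixed
#'   grammar, stable across runs.
#' @name messages
NULL

#' Closed taxonomy of semantic validation codes
#'
#' The semantic message codes the validator can emit, mirroring the issue
#' groups reported by DDL-based validation (value checks, referential
#' integrity, category/key checks, loop eligibility, data types, containers,
#' aliasing, deprecation, dictionary application scope).
#'
#' @return Character vector of code names.
#' @export
cif_message_taxonomy <- function() {
  c("value_outside_range", "value_outside_enum", "extra_su",
    "missing_foreign_key_item", "missing_foreign_key_value",
    "nonunique_simple_key", "nonunique_composite_key", "missing_key_item",
    "missing_mandatory_loop_item", "mixed_category_loop",
    "compromised_category_integrity", "unlooped_value_in_loop",
    "looped_value_outside_loop", "non_numeric_value", "type_violation",
    "forbidden_symbol", "value_not_in_list", "missing_top_level_container",
    "alias_value_mismatch", "unrecognized_data_name", "missing_su",
    "prohibited_su", "mismatching_su", "deprecated_item", "scope_violation")
}

#' Reader-level diagnostic codes
#'
#' Codes used for lexical/syntactic findings made while reading a file,
#' kept separate from the semantic taxonomy.
#'
#' @return Character vector of code names.
#' @export
cif_reader_codes <- function() {
  c("syntax_error", "duplicate_data_name", "long_line",
    "non_ascii_character", "dictionary_warning")
}

#' Construct a validation message
#'
#' @param code Message code; one of [cif_message_taxonomy()] or
#'   [cif_reader_codes()].
#' @param severity "NOTE", "WARNING" or "ERROR".
#' @param detail One-sentence human-readable description.
#' @param file Label of the originating file (path or "-" for stdin).
#' @param line 1-based line number, or NA when no position applies.
#' @param block Block path, e.g. "data_x" or "data_dic/save_item".
#' @param subjects Character vector of data names concerned (may be empty).
#' @param program Program name used when rendering; defaults to "ciflint".
#' @param type_kind For code "type_violation", the violated content type
#'   (e.g. "Integer"); NA otherwise.
#' @param suite Dictionary suite that produced the finding ("ddl1",
#'   "ddlm"), or NA for suite-independent findings (reader warnings,
#'   unrecognized names, scope checks). Both suites may legitimately
#'   report the same issue; the suite field keeps such findings distinct.
#' @return A list of class "cif_message".
#' @export
cif_message <- function(code, severity, detail, file = "-", line = NA_integer_,
                        block = "", subjects = character(),
                        program = "ciflint", type_kind = NA_character_,
                        suite = NA_character_) {
  stopifnot(code %in% c(cif_message_taxonomy(), cif_reader_codes()),
            severity %in% c("NOTE", "WARNING", "ERROR"))
  structure(list(program = program, file = file,
                 line = if (is.null(line)) NA_integer_ else as.integer(line),
                 block = block, severity = severity, code = code,
                 type_kind = type_kind, suite = suite,
                 subjects = as.character(subjects), detail = detail),
            class = "cif_message")
}

#' @export
print.cif_message <- function(x, ...) {
  cat(render_message(x), "\n", sep = "")
  invisible(x)
}

#' Render a message as its canonical one-line form
#'
#' Format: `<program>: <file>(<line>) <block>: <SEVERITY>, <detail>`.
#' The `(<line>)` segment is omitted when no position applies and the block
#' segment is omitted when empty. Embedded newlines in the detail are
#' escaped so the rendering is always a single line.
#'
#' @param m A `cif_message`.
#' @return A single character string without a trailing newline.
#' @export
render_message <- function(m) {
  pos <- if (is.na(m$line)) "" else sprintf("(%d)", m$line)
  blk <- if (nzchar(m$block)) paste0(" ", m$block) else ""
  detail <- gsub("\n", "\\\\n", m$detail, fixed = TRUE)
  sprintf("%s: %s%s%s: %s, %s", m$program, m$file, pos, blk, m$severity, detail)
}

#' Parse a rendered message line back into its fields
#'
#' Inverse of [render_message()] on the published grammar. Codes and
#' subjects are not recoverable from the rendering (they are carried in the
#' detail text informally); the structural fields are.
#'
#' @param line A line produced by [render_message()].
#' @return A list with program, file, line (integer or NA), block, severity
#'   and detail, or NULL if the line does not match the grammar.
#' @export
parse_message_line <- function(line) {
  re <- "^([^:]+): ([^():[:space:]]*)(?:\\(([0-9]+)\\))?(?: ([^:[:space:]]+))?: (NOTE|WARNING|ERROR), (.*)$"
  m <- regmatches(line, regexec(re, line, perl = TRUE))[[1]]
  if (length(m) == 0L) return(NULL)
  list(program = m[2], file = m[3],
       line = if (nzchar(m[4])) as.integer(m[4]) else NA_integer_,
       block = m[5], severity = m[6], detail = m[7])
}

msg_sort_key <- function(m) {
  paste(m$file, m$block,
        formatC(ifelse(is.na(m$line), 999999L, m$line), width = 7, flag = "0"),
        m$code, paste(m$subjects, collapse = ","), m$severity, m$detail,
        if (is.na(m$suite)) "" else m$suite,
        sep = "\r")
}

#' Sort and deduplicate a list of messages
#'
#' Stable order by (file, block, line, code, subjects); messages equal on
#' all fields are collapsed to one, so output is byte-identical across runs
#' and across input item/loop orderings (up to line numbers, which follow
#' the input layout).
#'
#' @param ms List of `cif_message` objects.
#' @return Sorted, deduplicated list of `cif_message` objects.
#' @export
sort_messages <- function(ms) {
  if (length(ms) == 0L) return(list())
  keys <- vapply(ms, msg_sort_key, character(1))
  ms <- ms[order(keys, method = "radix")]
  keys <- sort(keys, method = "radix")
  ms[!duplicated(keys)]
}

#' Convert messages to a data frame
#'
#' @param ms List of `cif_message` objects.
#' @return A data.frame with one row per message (subjects collapsed by
#'   comma), suitable for TSV export.
#' @export
messages_as_data_frame <- function(ms) {
  data.frame(
    file = vapply(ms, function(m) m$file, character(1)),
    line = vapply(ms, function(m) m$line, integer(1)),
    block = vapply(ms, function(m) m$block, character(1)),
    severity = vapply(ms, function(m) m$severity, character(1)),
    code = vapply(ms, function(m) m$code, character(1)),
    type_kind = vapply(ms, function(m) m$type_kind, character(1)),
    subject = vapply(ms, function(m) paste(m$subjects, collapse = ","),
                     character(1)),
    detail = vapply(ms, function(m) m$detail, character(1)),
    stringsAsFactors = FALSE)
}

# code + kind + subjects signature, used for multiset comparison of expected
# vs emitted messages with positions elided.
message_signature <- function(m) {
  paste(m$severity, m$code,
        if (is.na(m$type_kind)) "" else m$type_kind,
        paste(sort(m$subjects), collapse = ","), sep = "|")
}

#' Multiset signature of a message list (positions elided)
#'
#' Used to compare validator output against fixture manifests
#' layout-independently.
#'
#' @param ms List of `cif_message` objects.
#' @return Sorted character vector, one element per message.
#' @export
message_multiset <- function(ms) {
  sort(vapply(ms, message_signature, character(1)))
}
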