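#' @title Writing CIF files
#' @description Serializes a document back to CIF text, preserving the
#'   recorded quote style of every value, so that parse -> serialize ->
#'   parse is a fixed point (up to source positions).
#' @name cif_write
NULL

needs_quoting <- function(text) {
  nchar(text) == 0L || grepl("[[:space:]]", text) ||
    text %in% c("?", ".") ||
    substr(text, 1L, 1L) %in% c("'", "\"", "_", "#", "$", "[", "]", "{", "}") ||
    grepl("^(data_|save_|loop_|global_|stop_)", tolower(text))
}

format_value <- function(v, dialect) {
  if (v$variant == "special") return(v$text)
  if (v$variant == "list") {
    if (dialect != "cif20")
      stop("list values cannot be serialized to CIF 1.1")
    return(paste0("[",
                  paste(vapply(v$elements, format_value, character(1),
                               dialect = dialect), collapse = " "),
                  "]"))
  }
  if (v$variant == "table") {
    if (dialect != "cif20")
      stop("table values cannot be serialized to CIF 1.1")
    parts <- vapply(names(v$entries), function(k)
      paste0("'", k, "':", format_value(v$entries[[k]], dialect)),
      character(1))
    return(paste0("{", paste(parts, collapse = " "), "}"))
  }
  switch(v$quote_style,
         none = if (needs_quoting(v$text)) paste0("'", v$text, "'") else v$text,
         single = paste0("'", v$text, "'"),
         double = paste0("\"", v$text, "\""),
         triple = paste0("'''", v$text, "'''"),
         multiline = NA_character_)  # handled by the caller
}

serialize_block_body <- function(block, dialect, indent = "") {
  out <- character()
  push <- function(...) out <<- c(out, ...)
  for (key in names(block$items)) {
    e <- block$items[[key]]
    v <- e$value
    if (v$variant == "string" && v$quote_style == "multiline") {
      push(paste0(indent, e$orig_name))
      push(paste0(";", v$text), ";")
    } else {
      push(paste0(indent, e$orig_name, " ", format_value(v, dialect)))
    }
  }
  for (lp in block$loops) {
    push(paste0(indent, "loop_"))
    for (nm in lp$orig_names) push(paste0(indent, "    ", nm))
    for (p in lp$packets) {
      row <- character()
      flush_row <- function() {
        if (length(row)) {
          push(paste0(indent, "    ", paste(row, collapse = " ")))
          row <<- character()
        }
      }
      for (v in p) {
        if (v$variant == "string" && v$quote_style == "multiline") {
          flush_row()
          push(paste0(";", v$text), ";")
        } else {
          row <- c(row, format_value(v, dialect))
        }
      }
      flush_row()
    }
  }
  for (fr in block$frames) {
    push(paste0(indent, "save_", fr$name))
    push(serialize_block_body(fr, dialect, paste0(indent, "    ")))
    push(paste0(indent, "save_"))
  }
  out
}

#' Serialize a document to CIF text
#'
#' @param doc A `cif_document`.
#' @return Character vector of lines. A CIF 2.0 document starts with the
#'   magic comment; serializing list/table values into a CIF 1.1 document
#'   is an error.
#' @export
serialize_cif <- function(doc) {
  out <- character()
  if (doc$dialect == "cif20") out <- "#\\#CIF_2.0"
  for (b in doc$blocks) {
    header <- if (b$kind == "global") "global_" else paste0("data_", b$name)
    out <- c(out, header, serialize_block_body(b, doc$dialect))
  }
  out
}

#' Write a document to a file
#'
#' @param doc A `cif_document`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cif <- function(doc, path) {
  writeLines(serialize_cif(doc), path)
  invisible(path)
}
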