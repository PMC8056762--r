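#' @title CIF document model
#' @description Dialect-agnostic in-memory model for STAR/CIF files:
#'   values (with lexical quote style retained), loops, blocks with save
#'   frames, and whole documents. Data names are case-folded to lowercase
#'   at construction; the original spelling is retained for message
#'   rendering.
#' @name cif_model
NULL

#' Construct a CIF value
#'
#' @param text Raw lexical form (for strings and specials).
#' @param quote_style One of "none", "single", "double", "multiline",
#'   "triple".
#' @param variant One of "string", "special", "list", "table"; inferred
#'   when NULL: an unquoted `?` or `.` is special, otherwise a string.
#' @param elements Ordered list of `cif_value` (variant "list").
#' @param entries Named list of `cif_value` (variant "table").
#' @param line,col 1-based source position (NA for synthesized values).
#' @return A list of class "cif_value".
#' @export
cif_value <- function(text = "", quote_style = "none", variant = NULL,
                      elements = NULL, entries = NULL,
                      line = NA_integer_, col = NA_integer_) {
  if (is.null(variant)) {
    variant <- if (quote_style == "none" && text %in% c("?", "."))
      "special" else "string"
  }
  special_kind <- NA_character_
  if (variant == "special")
    special_kind <- if (identical(text, "?")) "unknown" else "inapplicable"
  structure(list(variant = variant, text = text, quote_style = quote_style,
                 special_kind = special_kind, elements = elements,
                 entries = entries, line = as.integer(line),
                 col = as.integer(col)),
            class = "cif_value")
}

#' Construct a loop
#'
#' @param names Data names (any case; folded to lowercase).
#' @param packets List of packets, each a list of `cif_value` of the same
#'   length as `names`.
#' @param line Source line of the `loop_` keyword.
#' @return A list of class "cif_loop".
#' @export
cif_loop <- function(names, packets, line = NA_integer_) {
  stopifnot(length(names) >= 1L,
            all(vapply(packets, length, 1L) == length(names)))
  structure(list(names = tolower(names), orig_names = names,
                 packets = packets, line = as.integer(line)),
            class = "cif_loop")
}

#' Construct a data block (or save frame)
#'
#' @param name Block or frame code.
#' @param items Named list (lowercase names) of entries, each a list with
#'   `value` (`cif_value`), `line`, `orig_name`.
#' @param loops List of `cif_loop`.
#' @param frames List of nested `cif_block` (save frames).
#' @param kind "data", "save" or "global".
#' @param line Source line of the block header.
#' @return A list of class "cif_block".
#' @export
cif_block <- function(name, items = list(), loops = list(), frames = list(),
                      kind = "data", line = NA_integer_) {
  structure(list(name = name, items = items, loops = loops, frames = frames,
                 kind = kind, line = as.integer(line)),
            class = "cif_block")
}

#' Construct a document
#'
#' @param blocks List of `cif_block`.
#' @param dialect "cif11" or "cif20".
#' @param warnings List of reader-level `cif_message`s.
#' @param file File label used in messages.
#' @return A list of class "cif_document".
#' @export
cif_document <- function(blocks = list(), dialect = "cif11",
                         warnings = list(), file = "-") {
  structure(list(dialect = dialect, blocks = blocks,
                 warnings = warnings, file = file),
            class = "cif_document")
}

#' @export
print.cif_document <- function(x, ...) {
  cat(sprintf("<cif_document> dialect=%s blocks=%d reader_warnings=%d\n",
              x$dialect, length(x$blocks), length(x$warnings)))
  for (b in x$blocks)
    cat(sprintf("  %s_%s: %d items, %d loops, %d frames\n", b$kind, b$name,
                length(b$items), length(b$loops), length(b$frames)))
  invisible(x)
}

# ---- accessors -----------------------------------------------------------

#' Add or replace an unlooped item in a block
#'
#' @param block A `cif_block`.
#' @param name Data name (any case).
#' @param value A `cif_value` or character scalar (wrapped unquoted).
#' @param line Optional source line.
#' @return The modified block.
#' @export
block_set_item <- function(block, name, value, line = NA_integer_) {
  if (is.character(value)) value <- cif_value(value)
  block$items[[tolower(name)]] <- list(value = value, line = as.integer(line),
                                       orig_name = name)
  block
}

#' Fetch an unlooped item's value by (case-insensitive) name
#'
#' @param block A `cif_block`.
#' @param name Data name.
#' @return A `cif_value`, or NULL when absent.
#' @export
block_get_item <- function(block, name) {
  e <- block$items[[tolower(name)]]
  if (is.null(e)) NULL else e$value
}

#' All data names present in a block (items and loops), lowercase
#'
#' @param block A `cif_block`.
#' @return Character vector.
#' @export
block_data_names <- function(block) {
  c(names(block$items), unlist(lapply(block$loops, function(l) l$names),
                               use.names = FALSE))
}

#' Loop column values for one data name
#'
#' @param loop A `cif_loop`.
#' @param name Data name (lowercase or any case).
#' @return List of `cif_value`, one per packet, or NULL when the loop does
#'   not contain the name.
#' @export
loop_column <- function(loop, name) {
  i <- match(tolower(name), loop$names)
  if (is.na(i)) return(NULL)
  lapply(loop$packets, function(p) p[[i]])
}

# loop index holding a data name, or NA
find_loop_of <- function(block, name) {
  name <- tolower(name)
  for (i in seq_along(block$loops))
    if (name %in% block$loops[[i]]$names) return(i)
  NA_integer_
}

# every occurrence of a data name in a block: list of lists
# (value, looped, loop_index, line)
occurrences_of <- function(block, name) {
  name <- tolower(name)
  out <- list()
  e <- block$items[[name]]
  if (!is.null(e))
    out[[length(out) + 1L]] <- list(value = e$value, looped = FALSE,
                                    loop_index = NA_integer_, line = e$line)
  for (i in seq_along(block$loops)) {
    col <- loop_column(block$loops[[i]], name)
    if (!is.null(col))
      for (v in col)
        out[[length(out) + 1L]] <- list(value = v, looped = TRUE,
                                        loop_index = i, line = v$line)
  }
  out
}

# all values of a data name anywhere in the block (unlooped + looped)
values_of <- function(block, name) {
  lapply(occurrences_of(block, name), function(o) o$value)
}

strip_positions <- function(x) {
  if (is.list(x)) {
    x$line <- NULL
    x$col <- NULL
    x[] <- lapply(x, strip_positions)
  }
  x
}

#' Compare two documents up to source positions
#'
#' @param a,b `cif_document` objects.
#' @return TRUE when equal apart from line/column positions and reader
#'   warnings.
#' @export
cif_doc_equal <- function(a, b) {
  a$warnings <- NULL; b$warnings <- NULL
  a$file <- NULL; b$file <- NULL
  identical(strip_positions(unclass(a)), strip_positions(unclass(b)))
}
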