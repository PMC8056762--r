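#' @title Validator driver
#' @description Runs the DDL1 and/or DDLm suites over parsed documents and
#'   implements the Unix-filter contract: messages to stdout, diagnostics
#'   to stderr, exit 0 when every input was processed (findings are data,
#'   not failure), 1 when an input failed to parse or a dictionary failed
#'   to load, 2 on usage error.
#' @name validate
NULL

#' Validate one parsed document
#'
#' For every data block: unrecognized-name detection against all supplied
#' dictionaries, the DDL1 suite when a DDL1 dictionary is given, and the
#' DDLm suite when a DDLm dictionary is given. Reader warnings of the
#' document are included. `global_` blocks and save frames in data files
#' are accepted syntactically but not validated.
#'
#' @param doc A `cif_document`.
#' @param ddl1 A `ddl1_dictionary` or NULL.
#' @param ddlm A `ddlm_dictionary` or NULL.
#' @param opts See [cif_validation_options()].
#' @return Sorted, deduplicated list of `cif_message`, with attribute
#'   `skipped_aliases`.
#' @export
validate_document <- function(doc, ddl1 = NULL, ddlm = NULL,
                              opts = cif_validation_options()) {
  dicts <- Filter(Negate(is.null), list(ddl1, ddlm))
  stopifnot(length(dicts) > 0L)
  out <- doc$warnings
  skipped <- character()
  for (block in doc$blocks) {
    if (block$kind != "data") next
    out <- c(out, check_unrecognized(block, dicts, file = doc$file))
    if (!is.null(ddl1))
      out <- c(out, validate_block_ddl1(block, ddl1, opts, file = doc$file))
    if (!is.null(ddlm)) {
      ms <- validate_block_ddlm(block, ddlm, opts, file = doc$file)
      skipped <- c(skipped, attr(ms, "skipped_aliases"))
      out <- c(out, ms)
    }
  }
  out <- sort_messages(out)
  attr(out, "skipped_aliases") <- unique(skipped)
  out
}

#' Application-scope validation of a DDLm dictionary file
#'
#' @param doc Parsed dictionary under validation.
#' @param reference_doc Parsed reference dictionary carrying the validity
#'   rules.
#' @return Sorted list of `cif_message`.
#' @export
validate_ddlm_dictionary <- function(doc, reference_doc) {
  sort_messages(m_check_application_scope(doc, reference_doc,
                                          file = doc$file))
}

#' Run the validator as a filter over files
#'
#' @param inputs Character vector of CIF file paths; empty means standard
#'   input.
#' @param ddl1_dicts Paths of DDL1 dictionaries (merged in order; first
#'   definition of a name wins).
#' @param ddlm_dicts Paths of DDLm dictionaries (frames merged in order).
#' @param import_path Directories searched for embedded dictionary
#'   imports.
#' @param options See [cif_validation_options()].
#' @param ddlm_reference Optional path of a DDLm reference dictionary;
#'   when given, every input is additionally checked for dictionary
#'   application scope.
#' @param output_format "text" (rendered lines) or "tsv".
#' @return Invisibly, a list with `exit_code`, `lines` (what was printed)
#'   and `messages`; lines are printed to `con`.
#' @param con Connection for validation output (stdout by default).
#' @export
cif_validate_files <- function(inputs = character(),
                               ddl1_dicts = character(),
                               ddlm_dicts = character(),
                               import_path = character(),
                               options = cif_validation_options(),
                               ddlm_reference = NULL,
                               output_format = c("text", "tsv"),
                               con = stdout()) {
  output_format <- match.arg(output_format)
  if (length(ddl1_dicts) == 0L && length(ddlm_dicts) == 0L) {
    message("usage error: at least one dictionary must be supplied")
    return(invisible(list(exit_code = 2L, lines = character(),
                          messages = list())))
  }
  exit_code <- 0L
  ddl1 <- NULL
  ddlm <- NULL
  locator <- import_path_locator(import_path)
  tryCatch({
    if (length(ddl1_dicts) > 0L)
      ddl1 <- load_ddl1(lapply(ddl1_dicts, read_cif))
    if (length(ddlm_dicts) > 0L) {
      docs <- lapply(ddlm_dicts, function(p)
        resolve_imports(read_cif(p), locator,
                        missing_policy =
                          if (length(import_path)) "fail" else "warn"))
      ddlm <- load_ddlm(docs)
    }
  }, error = function(e) {
    message("dictionary load failure: ", conditionMessage(e))
    exit_code <<- 1L
  })
  if (exit_code != 0L)
    return(invisible(list(exit_code = exit_code, lines = character(),
                          messages = list())))
  reference_doc <- if (!is.null(ddlm_reference)) read_cif(ddlm_reference)
  all_lines <- character()
  all_msgs <- list()
  targets <- if (length(inputs) == 0L) list("-") else as.list(inputs)
  for (input in targets) {
    ms <- tryCatch({
      doc <- if (identical(input, "-"))
        parse_cif(readLines("stdin", warn = FALSE), file = "-")
      else read_cif(input)
      ms <- validate_document(doc, ddl1, ddlm, options)
      for (id in attr(ms, "skipped_aliases"))
        message(sprintf(
          "%s: aliased values of %s occur in a looped list; alias agreement not checked",
          doc$file, id))
      if (!is.null(reference_doc))
        ms <- sort_messages(c(ms, validate_ddlm_dictionary(doc,
                                                           reference_doc)))
      ms
    }, cif_parse_error = function(e) {
      exit_code <<- 1L
      list(cif_message("syntax_error", "ERROR", e$detail,
                       file = if (identical(input, "-")) "-" else input,
                       line = e$line))
    }, error = function(e) {
      exit_code <<- 1L
      list(cif_message("syntax_error", "ERROR", conditionMessage(e),
                       file = if (identical(input, "-")) "-" else input))
    })
    all_msgs <- c(all_msgs, ms)
    all_lines <- c(all_lines, render_output(ms, output_format))
  }
  writeLines(all_lines, con)
  invisible(list(exit_code = exit_code, lines = all_lines,
                 messages = all_msgs))
}

render_output <- function(ms, output_format) {
  if (length(ms) == 0L) return(character())
  if (output_format == "text")
    return(vapply(ms, render_message, character(1)))
  df <- messages_as_data_frame(ms)
  apply(df, 1L, function(r) paste(r, collapse = "\t"))
}
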