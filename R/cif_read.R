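#' @title Reading CIF files
#' @description Tokenizer and parser for CIF 1.1 and CIF 2.0. The reader is
#'   error-correcting where safe (duplicate data names, overlong lines and
#'   stray non-ASCII characters are recorded as reader warnings); genuine
#'   grammar violations (unterminated quotes, loop headers without values,
#'   values outside any block) abort with a positioned parse error.
#' @name cif_read
NULL

cif_parse_error <- function(msg, file, line, col = NA_integer_) {
  stop(structure(class = c("cif_parse_error", "error", "condition"),
                 list(message = sprintf("%s:%s: %s", file, line, msg),
                      call = NULL, file = file, line = as.integer(line),
                      col = as.integer(col), detail = msg)))
}

#' Detect the dialect of a CIF text
#'
#' CIF 2.0 is recognised by the exact magic comment `#\#CIF_2.0` at the
#' start of the first line; anything else (including empty input) is
#' treated as CIF 1.1.
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines.
#' @return "cif11" or "cif20".
#' @export
detect_cif_dialect <- function(text) {
  lines <- split_cif_lines(text)
  if (length(lines) >= 1L && startsWith(lines[[1]], "#\\#CIF_2.0"))
    "cif20" else "cif11"
}

split_cif_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(text) == 0L) character() else text
}

# ---- tokenizer -----------------------------------------------------------

# Token: list(type, text, quote, line, col). Types: DATA SAVE SAVE_END LOOP
# GLOBAL NAME VALUE LBRACK RBRACK LBRACE RBRACE COLON
tokenize_cif <- function(lines, dialect, file, warn) {
  tokens <- list()
  nt <- 0L
  push <- function(type, text, quote, line, col) {
    nt <<- nt + 1L
    tokens[[nt]] <<- list(type = type, text = text, quote = quote,
                          line = line, col = col)
  }
  n <- length(lines)
  i <- 1L
  pos <- 1L
  brackets <- dialect == "cif20"
  while (i <= n) {
    ln <- lines[[i]]
    if (pos == 1L) {
      if (dialect == "cif11" && nchar(ln, type = "bytes") > 2048L)
        warn("long_line", sprintf("line exceeds 2048 characters"), i)
      if (dialect == "cif11" &&
          any(utf8ToInt(enc2utf8(ln)) > 127L, na.rm = TRUE))
        warn("non_ascii_character",
             "non-ASCII character in a CIF 1.1 file", i)
    }
    if (pos == 1L && startsWith(ln, ";")) {
      # multiline text field: runs to the next line starting with ';'
      start <- i
      parts <- substring(ln, 2L)
      j <- i + 1L
      closed <- FALSE
      while (j <= n) {
        if (startsWith(lines[[j]], ";")) { closed <- TRUE; break }
        parts <- c(parts, lines[[j]])
        j <- j + 1L
      }
      if (!closed)
        cif_parse_error("unterminated multiline text field", file, start)
      push("VALUE", paste(parts, collapse = "\n"), "multiline", start, 1L)
      i <- j
      pos <- 2L
      next
    }
    nc <- nchar(ln)
    if (pos > nc) { i <- i + 1L; pos <- 1L; next }
    ch <- substr(ln, pos, pos)
    if (ch %in% c(" ", "\t", "\r")) { pos <- pos + 1L; next }
    if (ch == "#") { i <- i + 1L; pos <- 1L; next }
    if (brackets && pos + 2L <= nc &&
        substr(ln, pos, pos + 2L) %in% c("'''", "\"\"\"")) {
      q3 <- substr(ln, pos, pos + 2L)
      close_at <- regexpr(q3, substr(ln, pos + 3L, nc), fixed = TRUE)
      if (close_at > 0L) {
        text <- substr(ln, pos + 3L, pos + 2L + close_at - 1L)
        push("VALUE", text, "triple", i, pos)
        pos <- pos + 3L + close_at - 1L + 3L
      } else {
        parts <- substring(ln, pos + 3L)
        j <- i + 1L
        done <- FALSE
        while (j <= n) {
          hit <- regexpr(q3, lines[[j]], fixed = TRUE)
          if (hit > 0L) {
            parts <- c(parts, substr(lines[[j]], 1L, hit - 1L))
            push("VALUE", paste(parts, collapse = "\n"), "triple", i, pos)
            i <- j
            pos <- hit + 3L
            done <- TRUE
            break
          }
          parts <- c(parts, lines[[j]])
          j <- j + 1L
        }
        if (!done)
          cif_parse_error("unterminated triple-quoted string", file, i, pos)
      }
      next
    }
    if (ch %in% c("'", "\"")) {
      close_at <- NA_integer_
      if (dialect == "cif20") {
        k <- pos + 1L
        while (k <= nc) {
          if (substr(ln, k, k) == ch) { close_at <- k; break }
          k <- k + 1L
        }
      } else {
        # CIF 1.1: a quote closes only when followed by whitespace or EOL
        k <- pos + 1L
        while (k <= nc) {
          if (substr(ln, k, k) == ch &&
              (k == nc || substr(ln, k + 1L, k + 1L) %in% c(" ", "\t", "\r"))) {
            close_at <- k
            break
          }
          k <- k + 1L
        }
      }
      if (is.na(close_at))
        cif_parse_error("unterminated quoted string", file, i, pos)
      push("VALUE", substr(ln, pos + 1L, close_at - 1L),
           if (ch == "'") "single" else "double", i, pos)
      pos <- close_at + 1L
      if (brackets && pos <= nc && substr(ln, pos, pos) == ":") {
        push("COLON", ":", "none", i, pos)
        pos <- pos + 1L
      }
      next
    }
    if (brackets && ch %in% c("[", "]", "{", "}")) {
      push(switch(ch, "[" = "LBRACK", "]" = "RBRACK",
                  "{" = "LBRACE", "}" = "RBRACE"), ch, "none", i, pos)
      pos <- pos + 1L
      next
    }
    # bare token
    k <- pos
    stop_chars <- if (brackets) c(" ", "\t", "\r", "[", "]", "{", "}")
                  else c(" ", "\t", "\r")
    while (k <= nc && !(substr(ln, k, k) %in% stop_chars)) k <- k + 1L
    word <- substr(ln, pos, k - 1L)
    lw <- tolower(word)
    if (startsWith(lw, "data_") && nchar(word) > 5L) {
      push("DATA", substring(word, 6L), "none", i, pos)
    } else if (lw == "save_") {
      push("SAVE_END", "", "none", i, pos)
    } else if (startsWith(lw, "save_")) {
      push("SAVE", substring(word, 6L), "none", i, pos)
    } else if (lw == "loop_") {
      push("LOOP", "", "none", i, pos)
    } else if (lw == "global_") {
      push("GLOBAL", "", "none", i, pos)
    } else if (startsWith(word, "_")) {
      push("NAME", word, "none", i, pos)
    } else {
      push("VALUE", word, "none", i, pos)
    }
    pos <- k
  }
  tokens
}

# ---- parser --------------------------------------------------------------

#' Parse CIF text into a document
#'
#' @param text Character vector of lines or a single string; may also be a
#'   file path when `is_path = TRUE`.
#' @param dialect "auto" (detect from the magic comment), "cif11" or
#'   "cif20".
#' @param file File label used in positions and messages.
#' @param is_path When TRUE, `text` is a path read with `readLines`.
#' @return A `cif_document`. Recoverable irregularities are recorded in
#'   `$warnings`; hard grammar violations signal a condition of class
#'   `cif_parse_error` carrying the source position.
#' @export
parse_cif <- function(text, dialect = "auto", file = "-", is_path = FALSE) {
  if (is_path) {
    file <- text
    text <- readLines(text, warn = FALSE)
  }
  lines <- split_cif_lines(text)
  if (dialect == "auto") dialect <- detect_cif_dialect(lines)
  warnings <- list()
  warn <- function(code, detail, line, block = "", subjects = character()) {
    warnings[[length(warnings) + 1L]] <<-
      cif_message(code, "WARNING", detail, file = file, line = line,
                  block = block, subjects = subjects)
  }
  tokens <- tokenize_cif(lines, dialect, file, warn)
  j <- 1L
  ntok <- length(tokens)
  peek <- function() if (j <= ntok) tokens[[j]] else NULL
  advance <- function() j <<- j + 1L

  read_value <- function() {
    tk <- peek()
    if (is.null(tk))
      cif_parse_error("expected a value, found end of input", file,
                      if (ntok) tokens[[ntok]]$line else 1L)
    if (tk$type == "VALUE") {
      advance()
      return(cif_value(tk$text, tk$quote, line = tk$line, col = tk$col))
    }
    if (tk$type == "LBRACK") {
      advance()
      elements <- list()
      repeat {
        nx <- peek()
        if (is.null(nx))
          cif_parse_error("unterminated list value", file, tk$line, tk$col)
        if (nx$type == "RBRACK") { advance(); break }
        elements[[length(elements) + 1L]] <- read_value()
      }
      return(cif_value(variant = "list", elements = elements,
                       line = tk$line, col = tk$col))
    }
    if (tk$type == "LBRACE") {
      advance()
      entries <- list()
      repeat {
        nx <- peek()
        if (is.null(nx))
          cif_parse_error("unterminated table value", file, tk$line, tk$col)
        if (nx$type == "RBRACE") { advance(); break }
        if (nx$type != "VALUE" || nx$quote %in% c("none"))
          cif_parse_error("table key must be a quoted string", file,
                          nx$line, nx$col)
        key <- nx$text
        advance()
        sep <- peek()
        if (is.null(sep) || sep$type != "COLON")
          cif_parse_error("expected ':' after table key", file,
                          nx$line, nx$col)
        advance()
        entries[[key]] <- read_value()
      }
      return(cif_value(variant = "table", entries = entries,
                       line = tk$line, col = tk$col))
    }
    cif_parse_error(sprintf("expected a value, found '%s'",
                            if (nzchar(tk$text)) tk$text else tk$type),
                    file, tk$line, tk$col)
  }

  blocks <- list()
  # stack of open containers; element 1 is the current data/global block,
  # further elements are open save frames
  stack <- list()
  block_path <- function() {
    if (length(stack) == 0L) return("")
    paste(vapply(seq_along(stack), function(k) {
      b <- stack[[k]]
      paste0(if (k == 1L) paste0(b$kind, "_") else "save_", b$name)
    }, character(1)), collapse = "/")
  }
  close_top <- function() {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <<- NULL
    if (length(stack) == 0L) {
      blocks[[length(blocks) + 1L]] <<- top
    } else {
      parent <- stack[[length(stack)]]
      parent$frames[[length(parent$frames) + 1L]] <- top
      stack[[length(stack)]] <<- parent
    }
    invisible(NULL)
  }
  close_all <- function() while (length(stack) > 0L) close_top()
  add_item <- function(name, value) {
    if (length(stack) == 0L)
      cif_parse_error(sprintf("data item '%s' outside any data block",
                              name), file, value$line)
    top <- stack[[length(stack)]]
    key <- tolower(name)
    if (key %in% block_data_names(top))
      warn("duplicate_data_name",
           sprintf("data name '%s' occurs more than once; last value kept",
                   name),
           value$line, block = block_path(), subjects = key)
    # last occurrence wins; an earlier looped occurrence stays in its loop
    top$items[[key]] <- list(value = value, line = value$line,
                             orig_name = name)
    stack[[length(stack)]] <<- top
  }

  while (!is.null(tk <- peek())) {
    if (tk$type == "DATA") {
      close_all()
      stack[[1L]] <- cif_block(tk$text, kind = "data", line = tk$line)
      advance()
    } else if (tk$type == "GLOBAL") {
      close_all()
      stack[[1L]] <- cif_block("", kind = "global", line = tk$line)
      advance()
    } else if (tk$type == "SAVE") {
      if (length(stack) == 0L)
        cif_parse_error("save frame outside any data block", file, tk$line)
      stack[[length(stack) + 1L]] <- cif_block(tk$text, kind = "save",
                                               line = tk$line)
      advance()
    } else if (tk$type == "SAVE_END") {
      if (length(stack) < 2L)
        cif_parse_error("save_ terminator without an open save frame",
                        file, tk$line)
      close_top()
      advance()
    } else if (tk$type == "NAME") {
      advance()
      v <- read_value()
      add_item(tk$text, v)
    } else if (tk$type == "LOOP") {
      loop_line <- tk$line
      advance()
      names_ <- character()
      while (!is.null(nx <- peek()) && nx$type == "NAME") {
        names_ <- c(names_, nx$text)
        advance()
      }
      if (length(names_) == 0L)
        cif_parse_error("loop_ without data names", file, loop_line)
      values <- list()
      while (!is.null(nx <- peek()) &&
             nx$type %in% c("VALUE", "LBRACK", "LBRACE")) {
        values[[length(values) + 1L]] <- read_value()
      }
      if (length(values) == 0L)
        cif_parse_error("loop_ header with no values", file, loop_line)
      if (length(values) %% length(names_) != 0L)
        cif_parse_error(sprintf(
          "loop value count (%d) is not a multiple of the data name count (%d)",
          length(values), length(names_)), file, loop_line)
      if (length(stack) == 0L)
        cif_parse_error("loop_ outside any data block", file, loop_line)
      npk <- length(values) %/% length(names_)
      packets <- vector("list", npk)
      for (p in seq_len(npk))
        packets[[p]] <- values[((p - 1L) * length(names_) + 1L):
                                 (p * length(names_))]
      top <- stack[[length(stack)]]
      for (nm in names_) {
        if (tolower(nm) %in% block_data_names(top))
          warn("duplicate_data_name",
               sprintf("data name '%s' occurs more than once; last value kept",
                       nm),
               loop_line, block = block_path(), subjects = tolower(nm))
      }
      # drop an earlier unlooped occurrence: the looped one is last
      for (nm in names_) top$items[[tolower(nm)]] <- NULL
      top$loops[[length(top$loops) + 1L]] <- cif_loop(names_, packets,
                                                      line = loop_line)
      stack[[length(stack)]] <- top
    } else {
      cif_parse_error(sprintf("value '%s' outside any data item", tk$text),
                      file, tk$line, tk$col)
    }
  }
  close_all()
  if (dialect == "cif11") {
    # dialect closure: the cif11 tokenizer emits no bracket tokens, so
    # list/table values cannot occur; assert anyway
    stopifnot(!any(vapply(blocks, block_has_compound, logical(1))))
  }
  cif_document(blocks, dialect = dialect, warnings = warnings, file = file)
}

block_has_compound <- function(block) {
  vals <- c(lapply(block$items, function(e) e$value),
            unlist(unlist(lapply(block$loops, function(l) l$packets),
                          recursive = FALSE),
                   recursive = FALSE))
  any(vapply(vals, function(v) v$variant %in% c("list", "table"),
             logical(1))) ||
    any(vapply(block$frames, block_has_compound, logical(1)))
}

#' Read a CIF file from disk
#'
#' @param path File path.
#' @param dialect See [parse_cif()].
#' @return A `cif_document`.
#' @export
read_cif <- function(path, dialect = "auto") {
  parse_cif(path, dialect = dialect, is_path = TRUE)
}
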