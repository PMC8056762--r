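#' @title Value semantics
#' @description Interpretation of CIF value strings: special values,
#'   numbers in concise standard-uncertainty notation, DDLm content types,
#'   type-aware normalization, and concatenated enumeration sets.
#' @name value_semantics
NULL

#' Classify a value as special or ordinary
#'
#' An unquoted `?` denotes an unknown value and an unquoted `.` an
#' inapplicable one; the same characters inside any kind of quotes are
#' ordinary one-character strings.
#'
#' @param v A `cif_value` (see [cif_value()]) or a bare character scalar
#'   (treated as unquoted).
#' @return One of "unknown", "inapplicable", "ordinary".
#' @export
classify_special <- function(v) {
  if (is.character(v)) v <- cif_value(v)
  if (v$variant == "special")
    return(if (v$special_kind == "unknown") "unknown" else "inapplicable")
  if (v$variant == "string" && v$quote_style == "none") {
    if (identical(v$text, "?")) return("unknown")
    if (identical(v$text, ".")) return("inapplicable")
  }
  "ordinary"
}

is_special_value <- function(v) classify_special(v) != "ordinary"

# ---- Concise standard-uncertainty notation -------------------------------

NUMBER_RE <- "^([+-]?)(([0-9]+)(\\.([0-9]*))?|\\.([0-9]+))([eE]([+-]?[0-9]+))?(\\(([0-9]+)\\))?$"

#' Parse a number written in concise standard-uncertainty notation
#'
#' Accepts an optional sign, a decimal mantissa, an optional exponent and an
#' optional parenthesized standard uncertainty, e.g. `12.5(3)` or
#' `-1.234e-2(5)`. The s.u. digits are scaled to the last decimal place of
#' the mantissa and then by the exponent, as in the concise notation used
#' throughout crystallographic data.
#'
#' @param raw Character scalar, not a special value.
#' @return A list of class `measured_number` with fields `value` (double),
#'   `su` (double or NA), `integral` (TRUE when the mantissa has neither a
#'   decimal point nor an exponent), or NULL when `raw` is not numeric.
#' @examples
#' parse_measured_number("12.5(3)")   # value 12.5, su 0.3
#' parse_measured_number("10")        # integral, no su
#' @export
parse_measured_number <- function(raw) {
  m <- regmatches(raw, regexec(NUMBER_RE, raw))[[1]]
  if (length(m) == 0L) return(NULL)
  sign <- if (m[2] == "-") -1 else 1
  mantissa <- m[3]
  has_point <- nzchar(m[5]) || nzchar(m[7])
  dec_digits <- if (nzchar(m[6])) nchar(m[6]) else if (nzchar(m[7])) nchar(m[7]) else 0L
  exp10 <- if (nzchar(m[9])) as.numeric(m[9]) else 0
  value <- sign * as.numeric(m[3]) * 10^exp10
  su <- NA_real_
  if (nzchar(m[10])) su <- as.numeric(m[11]) * 10^(-dec_digits) * 10^exp10
  structure(list(value = value, su = su,
                 integral = !has_point && !nzchar(m[8])),
            class = "measured_number")
}

has_concise_su <- function(raw) {
  n <- parse_measured_number(raw)
  !is.null(n) && !is.na(n$su)
}

#' Format a measured number in concise notation
#'
#' Inverse of [parse_measured_number()] for round-trip use in fixtures and
#' tests: formats `value` with `digits` decimal places and appends the s.u.
#' digits scaled to the last decimal place.
#'
#' @param value Numeric value.
#' @param su Standard uncertainty (NA for none).
#' @param digits Number of decimal places to print.
#' @return Character scalar.
#' @export
format_measured_number <- function(value, su = NA_real_, digits = 0L) {
  base <- formatC(value, format = "f", digits = digits)
  if (is.na(su)) return(base)
  su_digits <- round(su * 10^digits)
  paste0(base, "(", su_digits, ")")
}

# ---- Content-type registry ----------------------------------------------

SYMOP_AXIS_RE <- "[+-]?([xyz]|[0-9]+(/[0-9]+)?)([+-]([xyz]|[0-9]+(/[0-9]+)?))*"

check_date_string <- function(raw) {
  if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", raw)) return(FALSE)
  !is.na(as.Date(raw, format = "%Y-%m-%d", optional = TRUE))
}

parse_datetime_string <- function(raw) {
  re <- paste0("^([0-9]{4}-[0-9]{2}-[0-9]{2})",
               "(?:T([0-9]{2}):([0-9]{2})(?::([0-9]{2})(\\.[0-9]+)?)?",
               "(Z|[+-][0-9]{2}:[0-9]{2})?)?$")
  m <- regmatches(raw, regexec(re, raw, perl = TRUE))[[1]]
  if (length(m) == 0L) return(NULL)
  if (!check_date_string(m[2])) return(NULL)
  has_time <- nzchar(m[3])
  hh <- if (has_time) as.integer(m[3]) else NA_integer_
  mm <- if (has_time) as.integer(m[4]) else NA_integer_
  ss <- if (nzchar(m[5])) as.numeric(m[5]) + as.numeric(paste0("0", m[6], collapse = "")) else
    if (has_time) 0 else NA_real_
  if (has_time && (hh > 23 || mm > 59 || (!is.na(ss) && ss >= 61))) return(NULL)
  tz <- m[7]
  list(date = m[2], has_time = has_time, hh = hh, mm = mm, ss = ss,
       tz = if (nzchar(tz)) tz else NA_character_)
}

content_type_checkers <- function() {
  list(
    Text = function(raw) TRUE,
    Code = function(raw) !grepl("[[:space:]]", raw),
    Name = function(raw) grepl("^[A-Za-z_][A-Za-z0-9_.%-]*$", raw),
    Tag  = function(raw) grepl("^_[^[:space:]]+$", raw),
    Uri  = function(raw) grepl("^[A-Za-z][A-Za-z0-9+.-]*:[^[:space:]]+$", raw),
    Date = check_date_string,
    DateTime = function(raw) !is.null(parse_datetime_string(raw)),
    Version = function(raw) grepl("^[0-9]+(\\.[0-9]+)*([A-Za-z0-9_.-]*)$", raw),
    Symop = function(raw) {
      axes <- strsplit(raw, ",", fixed = TRUE)[[1]]
      length(axes) == 3L &&
        all(grepl(paste0("^", SYMOP_AXIS_RE, "$"), tolower(trimws(axes))))
    },
    Range = function(raw) grepl("^[^:[:space:]]*:[^:[:space:]]*$", raw),
    Count = function(raw) {
      n <- parse_measured_number(raw)
      !is.null(n) && n$integral && n$value >= 0
    },
    Index = function(raw) {
      n <- parse_measured_number(raw)
      !is.null(n) && n$integral && n$value >= 1
    },
    Integer = function(raw) {
      n <- parse_measured_number(raw)
      !is.null(n) && n$integral
    },
    Real = function(raw) !is.null(parse_measured_number(raw)),
    Imag = function(raw) grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)[jJ]$", raw),
    Complex = function(raw)
      grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([+-]([0-9]+(\\.[0-9]*)?|\\.[0-9]+)[jJ])?$", raw)
  )
}

#' The content-type registry
#'
#' Data-driven table of DDLm content types: syntax class and case rule.
#' Types not present in the registry degrade to Text (always valid) with a
#' diagnostic, so dictionaries using unforeseen types remain loadable. Text
#' is case-sensitive; identifier-like types (Code, Name, Tag) fold case, a
#' local convention since DDLm itself enumerates case sensitivity per type
#' only in prose.
#'
#' @return data.frame with columns `name`, `case_sensitive`, `numeric`.
#' @export
content_type_registry <- function() {
  data.frame(
    name = c("Text", "Code", "Name", "Tag", "Uri", "Date", "DateTime",
             "Version", "Symop", "Range", "Count", "Index", "Integer",
             "Real", "Imag", "Complex"),
    case_sensitive = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                       TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                       TRUE, FALSE, FALSE),
    numeric = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    whitespace_free = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                        FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                        FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

registry_row <- function(type) {
  reg <- content_type_registry()
  i <- match(type, reg$name)
  if (is.na(i)) NULL else reg[i, ]
}

#' Check a raw value against a DDLm content type
#'
#' Integer (and the integer-like Count/Index) reject any form with a
#' decimal point or exponent; Real accepts integers; Date and DateTime
#' follow calendar validity; Symop follows the "x,y,z" coordinate-triplet
#' grammar with optional rational translations. For whitespace-free types a
#' value containing whitespace yields the `forbidden_symbol` outcome.
#' Unregistered type names degrade to Text (always ok).
#'
#' @param raw Character scalar (an ordinary, non-special value). Values in
#'   concise s.u. notation should be stripped of the s.u. by the caller if
#'   the type does not admit it; numeric checkers here accept a trailing
#'   parenthesized s.u.
#' @param type Content-type name, e.g. "Integer".
#' @return List with `ok` (logical) and, when not ok, `violation` (one of
#'   "non_numeric", "type_violation", "forbidden_symbol") and `kind` (the
#'   type name).
#' @export
check_content_type <- function(raw, type) {
  row <- registry_row(type)
  if (is.null(row)) return(list(ok = TRUE))
  if (row$whitespace_free && grepl("[[:space:]]", raw))
    return(list(ok = FALSE, violation = "forbidden_symbol", kind = type))
  chk <- content_type_checkers()[[type]]
  if (isTRUE(chk(raw))) list(ok = TRUE)
  else list(ok = FALSE, violation = "type_violation", kind = type)
}

#' Normalize a value for type-aware comparison
#'
#' Case-insensitive types fold case; numeric types canonicalize to a fixed
#' numeral form (s.u. ignored); DateTime values with a zone offset convert
#' to UTC while zone-less ones stay floating (never equal to a zoned one).
#' The mapping is idempotent. Values that do not pass the type's syntax are
#' returned unchanged (apart from case folding for case-insensitive types).
#'
#' @param raw Character scalar.
#' @param type Content-type name; defaults to "Text" (identity).
#' @return Canonical character scalar.
#' @export
normalize_value <- function(raw, type = "Text") {
  row <- registry_row(type)
  if (is.null(row)) return(raw)
  out <- raw
  if (row$numeric) {
    n <- parse_measured_number(raw)
    if (!is.null(n)) out <- format(n$value, digits = 15, scientific = FALSE,
                                   trim = TRUE)
  } else if (type == "DateTime") {
    p <- parse_datetime_string(raw)
    if (!is.null(p)) {
      if (!p$has_time) {
        out <- p$date
      } else if (is.na(p$tz)) {
        out <- sprintf("%sT%02d:%02d:%06.3f", p$date, p$hh, p$mm, p$ss)
      } else {
        off_min <- if (p$tz == "Z") 0L else {
          sgn <- if (substr(p$tz, 1, 1) == "-") -1L else 1L
          sgn * (as.integer(substr(p$tz, 2, 3)) * 60L +
                   as.integer(substr(p$tz, 5, 6)))
        }
        frac <- p$ss - floor(p$ss)
        t <- as.POSIXct(sprintf("%s %02d:%02d:%02d", p$date, p$hh, p$mm,
                                as.integer(floor(p$ss))), tz = "UTC") -
          off_min * 60
        out <- sprintf("%sT%s%sZ", format(t, "%Y-%m-%d", tz = "UTC"),
                       format(t, "%H:%M:%S", tz = "UTC"),
                       substring(sprintf("%.3f", frac), 2))
      }
    }
  }
  if (!row$case_sensitive) out <- tolower(out)
  out
}

#' Tokenize a concatenated enumeration value
#'
#' Splits `raw` into members of `allowed` by greedy longest-match scanning
#' left to right (ties broken by declaration order). Concatenated
#' enumeration sets are a legacy dictionary feature: some items (classically
#' the refinement-flags item, states S, G, R, D, T, U, P, .) permit values
#' like "PDU" that concatenate several set members.
#'
#' @param raw Character scalar.
#' @param allowed Character vector of permitted enumeration values.
#' @return List with `ok`; on success `tokens` (character vector), on
#'   failure `offset` (1-based position of the unconsumable residue).
#' @export
tokenize_concatenated <- function(raw, allowed) {
  stopifnot(length(allowed) > 0L)
  ord <- order(-nchar(allowed), seq_along(allowed))
  allowed <- allowed[ord]
  pos <- 1L
  n <- nchar(raw)
  tokens <- character()
  while (pos <= n) {
    hit <- NA_character_
    for (a in allowed) {
      la <- nchar(a)
      if (pos + la - 1L <= n && substr(raw, pos, pos + la - 1L) == a) {
        hit <- a
        break
      }
    }
    if (is.na(hit)) return(list(ok = FALSE, offset = pos))
    tokens <- c(tokens, hit)
    pos <- pos + nchar(hit)
  }
  list(ok = TRUE, tokens = tokens)
}
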