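test_that("concise s.u. notation parses with correct scaling", {
  n <- parse_measured_number("12.5(3)")
  expect_equal(n$value, 12.5)
  expect_equal(n$su, 0.3)
  expect_false(n$integral)

  n <- parse_measured_number("10")
  expect_equal(n$value, 10)
  expect_true(n$integral)
  expect_true(is.na(n$su))

  expect_null(parse_measured_number("24 C"))
  expect_null(parse_measured_number("136-145"))
  expect_null(parse_measured_number(""))

  n <- parse_measured_number("-.5(2)")
  expect_equal(n$value, -0.5)
  expect_equal(n$su, 0.2)
})

test_that("s.u. scaling on exponent forms matches an independent textual expansion", {
  # oracle: rewrite the mantissa with all digits zeroed and the su digits
  # right-aligned into its last decimal places, then apply the exponent
  expand_su <- function(mantissa, su_digits, exp10) {
    zeroed <- gsub("[0-9]", "0", mantissa)
    dec <- sub("^[^.]*\\.?", "", zeroed)
    head_len <- nchar(dec) - nchar(su_digits)
    su_text <- paste0("0.", strrep("0", head_len), su_digits)
    as.numeric(su_text) * 10^exp10
  }
  cases <- list(list("-1.234e-2(5)", "1.234", "5", -2),
                list("9.87e3(12)", "9.87", "12", 3),
                list("0.250(25)", "0.250", "25", 0))
  for (cs in cases) {
    n <- parse_measured_number(cs[[1]])
    expect_equal(n$su, expand_su(cs[[2]], cs[[3]], cs[[4]]))
  }
  expect_equal(parse_measured_number("-1.234e-2(5)")$value, -0.01234)
})

test_that("formatting and reparsing a measured number is exact for short s.u.", {
  set.seed(41)
  for (i in 1:50) {
    digits <- sample(0:4, 1)
    value <- round(stats::runif(1, -50, 50), digits)
    su <- sample(1:99, 1) * 10^(-digits)
    txt <- format_measured_number(value, su, digits)
    n <- parse_measured_number(txt)
    expect_equal(n$value, value)
    expect_equal(n$su, su)
  }
})

test_that("content types follow their declared syntax", {
  expect_false(check_content_type("3.0", "Integer")$ok)
  expect_equal(check_content_type("3.0", "Integer")$violation,
               "type_violation")
  expect_true(check_content_type("3", "Integer")$ok)
  expect_true(check_content_type("3.0", "Real")$ok)
  expect_true(check_content_type("x,y,z", "Symop")$ok)
  expect_true(check_content_type("-x+1/2,y,z+1/2", "Symop")$ok)
  expect_false(check_content_type("x,y", "Symop")$ok)
  expect_false(check_content_type("x,y,w", "Symop")$ok)
  expect_false(check_content_type("2021-13-01", "Date")$ok)
  expect_true(check_content_type("2021-12-01", "Date")$ok)
  expect_false(check_content_type("2021-02-29", "Date")$ok)
  expect_true(check_content_type("2020-02-29", "Date")$ok)
  expect_true(check_content_type("2021-02-14T12:00:00Z", "DateTime")$ok)
  expect_false(check_content_type("2021-02-14T25:00:00", "DateTime")$ok)
  expect_true(check_content_type("https://example.org/x", "Uri")$ok)
  expect_false(check_content_type("not a uri", "Uri")$ok)
  expect_true(check_content_type("3.0.1", "Version")$ok)
  expect_equal(check_content_type("two words", "Code")$violation,
               "forbidden_symbol")
  expect_true(check_content_type("monoclinic", "Code")$ok)
  expect_false(check_content_type("-1", "Count")$ok)
  expect_false(check_content_type("0", "Index")$ok)
  expect_true(check_content_type("1", "Index")$ok)
  # an unregistered type degrades to always-ok
  expect_true(check_content_type("anything at all", "NoSuchType")$ok)
})

test_that("the symop grammar matches an independent regular grammar", {
  axis <- "[+-]?([xyz]|[0-9]+(/[0-9]+)?)([+-]([xyz]|[0-9]+(/[0-9]+)?))*"
  oracle <- function(s) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    length(parts) == 3L &&
      all(grepl(paste0("^", axis, "$"), tolower(parts)))
  }
  cases <- c("x,y,z", "-x+1/2,y,z+1/2", "X,-Y,Z", "x+y,z,x", "1/2+x,y,z",
             "x,y", "x;y;z", "w,y,z", "x,,z", "x+,y,z")
  for (cs in cases)
    expect_equal(check_content_type(cs, "Symop")$ok, oracle(cs), info = cs)
})

test_that("Integer acceptance implies Real acceptance (type subsumption)", {
  set.seed(7)
  pool <- c(as.character(sample(-500:500, 40)),
            sprintf("%.3f", stats::runif(20, -10, 10)),
            "1e5", "2.5e-3", "abc", "12.5(3)", "10(2)", "-7", "0.0")
  for (x in pool)
    if (check_content_type(x, "Integer")$ok)
      expect_true(check_content_type(x, "Real")$ok, info = x)
})

test_that("normalization folds case, canonicalizes numerals and time zones", {
  expect_equal(normalize_value("Monoclinic", "Code"), "monoclinic")
  expect_equal(normalize_value("1.50", "Real"), normalize_value("1.5", "Real"))
  expect_equal(normalize_value("2021-02-14T12:00:00+00:00", "DateTime"),
               normalize_value("2021-02-14T12:00:00Z", "DateTime"))
  expect_equal(normalize_value("2021-02-14T14:30:00+02:30", "DateTime"),
               normalize_value("2021-02-14T12:00:00Z", "DateTime"))
  # a zone-less time stays floating and never equals a zoned one
  expect_false(normalize_value("2021-02-14T12:00:00", "DateTime") ==
                 normalize_value("2021-02-14T12:00:00Z", "DateTime"))
})

test_that("normalization is idempotent across the registry", {
  set.seed(13)
  samples <- list(
    Text = c("Some Text", "x"), Code = c("Monoclinic", "A_b-C"),
    Name = c("Alpha", "beta_1"), Tag = c("_cell_length_a", "_X.Y"),
    Uri = c("https://example.org/A", "ftp://x/y"),
    Date = c("2021-02-14", "1999-12-31"),
    DateTime = c("2021-02-14T12:00:00+01:00", "2021-02-14T12:00:00",
                 "2021-02-14"),
    Version = c("3.0.1", "2.4"),
    Symop = c("X,Y,Z", "-x+1/2,y,z"),
    Count = c("7", "0"), Index = c("3", "12"),
    Integer = c("-4", "17"), Real = c("1.50", "2.5e-3", "12.5(3)"))
  for (type in names(samples))
    for (x in samples[[type]]) {
      once <- normalize_value(x, type)
      expect_identical(normalize_value(once, type), once,
                       info = paste(type, x))
    }
})

test_that("greedy tokenization matches exhaustive search on prefix-free sets", {
  flags <- c("S", "G", "R", "D", "T", "U", "P", ".")
  r <- tokenize_concatenated("PDU", flags)
  expect_true(r$ok)
  expect_equal(r$tokens, c("P", "D", "U"))
  expect_equal(tokenize_concatenated("S", flags)$tokens, "S")
  bad <- tokenize_concatenated("PXU", flags)
  expect_false(bad$ok)
  expect_equal(bad$offset, 2L)

  set.seed(99)
  for (i in 1:60) {
    alphabet <- sample(LETTERS[1:6], sample(3:5, 1))
    # prefix-free by construction: distinct single letters
    raw <- paste(sample(c(alphabet, "X"), sample(1:6, 1), replace = TRUE),
                 collapse = "")
    expect_equal(tokenize_concatenated(raw, alphabet)$ok,
                 brute_tokenize(raw, alphabet),
                 info = paste(raw, paste(alphabet, collapse = "")))
  }
})

test_that("longest match wins for multi-character set members", {
  r <- tokenize_concatenated("abcab", c("a", "ab", "c"))
  expect_true(r$ok)
  expect_equal(r$tokens, c("ab", "c", "ab"))
})
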