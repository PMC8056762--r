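test_that("dialect detection keys on the CIF 2.0 magic comment", {
  expect_equal(detect_cif_dialect("#\\#CIF_2.0"), "cif20")
  expect_equal(detect_cif_dialect(c("#\\#CIF_2.0 extra", "data_x")), "cif20")
  expect_equal(detect_cif_dialect("data_test"), "cif11")
  expect_equal(detect_cif_dialect(character()), "cif11")
  expect_equal(detect_cif_dialect(c("# comment", "#\\#CIF_2.0")), "cif11")
})

test_that("plain CIF 1.1 grammar maps onto the document model", {
  doc <- parse_cif(c("data_x", "_a 1", "loop_", "_b", "_c",
                     "1 2", "3 4"))
  expect_length(doc$blocks, 1L)
  b <- doc$blocks[[1]]
  expect_equal(b$name, "x")
  expect_length(b$items, 1L)
  expect_length(b$loops, 1L)
  expect_length(b$loops[[1]]$packets, 2L)
  expect_equal(b$loops[[1]]$names, c("_b", "_c"))
  expect_equal(block_get_item(b, "_A")$text, "1")
})

test_that("bare ? and . parse as special values, quoted ones as strings", {
  b <- first_block(c("data_x", "_u ?", "_i .", "_q '?'", "_d \".\""))
  expect_equal(block_get_item(b, "_u")$variant, "special")
  expect_equal(block_get_item(b, "_u")$special_kind, "unknown")
  expect_equal(block_get_item(b, "_i")$special_kind, "inapplicable")
  expect_equal(block_get_item(b, "_q")$variant, "string")
  expect_equal(classify_special(block_get_item(b, "_q")), "ordinary")
  expect_equal(classify_special(block_get_item(b, "_u")), "unknown")
})

test_that("hard grammar violations abort with a positioned parse error", {
  expect_error(parse_cif(c("data_x", "loop_", "_b", "_c")),
               class = "cif_parse_error")
  expect_error(parse_cif(c("data_x", "loop_", "1 2")),
               class = "cif_parse_error")
  expect_error(parse_cif(c("_a 1")), class = "cif_parse_error")
  expect_error(parse_cif(c("data_x", "_a 'unterminated")),
               class = "cif_parse_error")
  expect_error(parse_cif(c("data_x", "_t", ";open", "never closed")),
               class = "cif_parse_error")
  err <- tryCatch(parse_cif(c("data_x", "loop_", "_b"), file = "f.cif"),
                  cif_parse_error = identity)
  expect_equal(err$line, 2L)
  expect_equal(err$file, "f.cif")
})

test_that("recoverable irregularities become reader warnings, not failures", {
  doc <- parse_cif(c("data_x", "_a 1", "_a 2"))
  expect_length(doc$warnings, 1L)
  expect_equal(doc$warnings[[1]]$code, "duplicate_data_name")
  expect_equal(block_get_item(doc$blocks[[1]], "_a")$text, "2")

  doc2 <- parse_cif(c("data_x", "_a café"))
  expect_true("non_ascii_character" %in% codes_of(doc2$warnings))

  doc3 <- parse_cif(c("data_x", paste0("_a ", strrep("y", 2100))))
  expect_true("long_line" %in% codes_of(doc3$warnings))
})

test_that("CIF 2.0 lists, tables, triple quotes and save frames parse", {
  doc <- parse_cif(c("#\\#CIF_2.0", "data_y",
                     "_m [[1.0 0.0] [0.0 2.0]]",
                     "_tb {'k':3 'j':[1 2]}",
                     "_s '''tri ple'''",
                     "save_fr", "_inner 5", "save_"))
  b <- doc$blocks[[1]]
  m <- block_get_item(b, "_m")
  expect_equal(m$variant, "list")
  expect_length(m$elements, 2L)
  expect_equal(m$elements[[1]]$elements[[2]]$text, "0.0")
  tb <- block_get_item(b, "_tb")
  expect_equal(tb$variant, "table")
  expect_equal(tb$entries$k$text, "3")
  expect_equal(tb$entries$j$variant, "list")
  expect_equal(block_get_item(b, "_s")$text, "tri ple")
  expect_length(b$frames, 1L)
  expect_equal(block_get_item(b$frames[[1]], "_inner")$text, "5")
})

test_that("multiline text fields keep their content and quote style", {
  b <- first_block(c("data_x", "_t", ";first", "second", ";"))
  v <- block_get_item(b, "_t")
  expect_equal(v$quote_style, "multiline")
  expect_equal(v$text, "first\nsecond")
})

test_that("serialization round-trips every fixture in both dialects", {
  corpus <- c(list(make_valid_cif(11)$cif_text,
                   toy$ddl1_text, toy$ddlm_text, toy$reference_text),
              lapply(violation_codes()[1:8], function(code)
                inject_violations(make_valid_cif(5), code)$cif_text))
  for (txt in corpus) {
    d1 <- parse_cif(txt)
    d2 <- parse_cif(serialize_cif(d1))
    expect_true(cif_doc_equal(d1, d2))
    expect_true(cif_doc_equal(d2, parse_cif(serialize_cif(d2))))
  }
})

test_that("serializing compound values into CIF 1.1 fails", {
  doc <- parse_cif(c("#\\#CIF_2.0", "data_y", "_m [1 2]"))
  doc$dialect <- "cif11"
  expect_error(serialize_cif(doc), "CIF 1.1")
})

test_that("special values serialize as bare characters", {
  doc <- parse_cif(c("data_x", "_u ?", "_i ."))
  txt <- serialize_cif(doc)
  expect_true(any(grepl("^_u \\?$", txt)))
  expect_true(any(grepl("^_i \\.$", txt)))
})

test_that("item positions are non-decreasing in document order", {
  doc <- parse_cif(make_valid_cif(3)$cif_text)
  b <- doc$blocks[[1]]
  lines <- vapply(b$items, function(e) e$line, integer(1))
  expect_true(all(diff(lines) >= 0))
  loop_lines <- vapply(b$loops, function(l) l$line, integer(1))
  expect_true(all(diff(loop_lines) >= 0))
})

test_that("cif11 documents never contain list or table values", {
  for (seed in 1:5) {
    doc <- parse_cif(toy$ddl1_text)
    expect_equal(doc$dialect, "cif11")
    has_compound <- function(b)
      any(vapply(c(lapply(b$items, function(e) e$value$variant),
                   "string"),
                 function(v) v %in% c("list", "table"), logical(1)))
    expect_false(any(vapply(doc$blocks, has_compound, logical(1))))
  }
})

test_that("global_ blocks are accepted syntactically", {
  doc <- parse_cif(c("global_", "_g 1", "data_x", "_a 2"))
  expect_length(doc$blocks, 2L)
  expect_equal(doc$blocks[[1]]$kind, "global")
  expect_equal(doc$blocks[[2]]$kind, "data")
})
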