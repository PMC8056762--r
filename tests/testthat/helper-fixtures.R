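# Toy dictionaries are fixed study conditions; load them once per session.
toy <- make_toy_dictionaries()
toy_dicts <- load_toy_dictionaries(toy)

# parse a character vector of CIF lines and return the first block
first_block <- function(lines, dialect = "auto") {
  parse_cif(lines, dialect = dialect)$blocks[[1]]
}

codes_of <- function(ms) vapply(ms, function(m) m$code, character(1))

# a minimal DDL1 dictionary from definition blocks given as text
mini_ddl1 <- function(...) load_ddl1(parse_cif(c(...)))

# a minimal DDLm dictionary wrapped in the CIF 2.0 preamble
mini_ddlm <- function(...) {
  load_ddlm(parse_cif(c("#\\#CIF_2.0", "data_mini", ...)))
}

# brute-force oracles -----------------------------------------------------

# all-pairs scan for duplicated key tuples in a loop
brute_duplicate_tuples <- function(lp, key_names, normalizer = identity) {
  idx <- match(tolower(key_names), lp$names)
  tuples <- vapply(lp$packets, function(p)
    paste(vapply(idx, function(i) normalizer(p[[i]]$text), character(1)),
          collapse = "\r"), character(1))
  dups <- character()
  n <- length(tuples)
  if (n >= 2L)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        if (tuples[[i]] == tuples[[j]]) dups <- c(dups, tuples[[i]])
  sort(unique(dups))
}

# set-scan oracle for foreign-key value violations
brute_fk_missing <- function(child_vals, parent_vals, normalizer = identity) {
  child_vals <- vapply(child_vals, normalizer, character(1))
  parent_vals <- vapply(parent_vals, normalizer, character(1))
  child_vals[!(child_vals %in% parent_vals)]
}

# exhaustive-search tokenizer used as the oracle for greedy segmentation
brute_tokenize <- function(raw, allowed) {
  if (nchar(raw) == 0L) return(TRUE)
  for (a in allowed) {
    la <- nchar(a)
    if (la <= nchar(raw) && substr(raw, 1L, la) == a &&
        brute_tokenize(substring(raw, la + 1L), allowed))
      return(TRUE)
  }
  FALSE
}
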