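vocabs <- default_vocabularies()

test_that("status terms standardize via the translation table", {
  v <- vocabs$establishmentMeans
  out <- standardize_term(c("alien", "introduced", "weird-status-xyz", NA, ""), v, "SRC")
  expect_equal(as.character(out), c("introduced", "introduced", NA, NA, NA))
  rep <- attr(out, "report")
  expect_true(all(rep$matched[rep$verbatim %in% c("alien", "introduced")]))
  expect_false(rep$matched[rep$verbatim == "weird-status-xyz"])
  expect_equal(rep$source_name[1], "SRC")
})

test_that("standardization is idempotent on canonical terms", {
  for (field in names(vocabs)) {
    v <- vocabs[[field]]
    canon <- unique(v$canonical)
    once <- as.character(standardize_term(canon, v))
    twice <- as.character(standardize_term(once, v))
    expect_equal(once, canon, info = field)
    expect_equal(twice, once, info = field)
  }
})

test_that("lookup is case-, whitespace- and diacritic-insensitive", {
  v <- vocabs$establishmentMeans
  expect_equal(as.character(standardize_term(c("  ALIEN ", "NatiVe", "naïve"), v)),
               c("introduced", "native", NA))
})

test_that("multi-valued habitat cells standardize token-wise, deduplicated and sorted", {
  v <- vocabs$habitat
  out <- standardize_habitat(c("freshwater; marine", "sea", "marine, sea", "", "swamp"),
                             v, source_name = "SRC")
  expect_equal(as.character(out),
               c("freshwater; marine", "marine", "marine", NA, NA))
  rep <- attr(out, "report")
  expect_false(rep$matched[rep$verbatim == "swamp"])
})

test_that("distinct matched plus unmatched verbatims partition the observed terms", {
  v <- vocabs$occurrenceStatus
  verb <- c("present", "extant", "gone", "Gone", "absent", "present", "mystery")
  out <- standardize_term(verb, v, "SRC")
  rep <- attr(out, "report")
  expect_equal(sum(rep$count), sum(verb != ""))
  expect_equal(nrow(rep), length(unique(verb)))
  expect_equal(sum(rep$matched) + sum(!rep$matched), nrow(rep))
})
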