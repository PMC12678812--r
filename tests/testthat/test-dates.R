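test_that("single years, ranges and dialect forms reduce to one year", {
  got <- standardize_event_date(c(
    "2010", "1900-1910", "1900-1901", "1987-06-03", "c. 1850", "ca 1850",
    "1950s", "03.06.1987", "1900 to 1904", "1900–1910"
  ))
  expect_equal(as.integer(got),
               c(2010L, 1905L, 1900L, 1987L, 1850L, 1850L,
                 1950L, 1987L, 1902L, 1905L))
})

test_that("non-integer range means truncate toward the earlier year", {
  # brute-force check of the rounding rule over many ranges
  for (lo in c(1800L, 1899L, 1950L)) {
    for (span in 1:7) {
      got <- as.integer(standardize_event_date(sprintf("%d-%d", lo, lo + span)))
      expect_equal(got, as.integer(floor((lo + lo + span) / 2)))
      expect_gte(got, lo); expect_lte(got, lo + span)
    }
  }
})

test_that("unparseable and implausible dates are reported, not guessed", {
  got <- standardize_event_date(c("soon", "999", "12345", "3020", ""),
                                bounds = c(1000L, 2026L))
  expect_true(all(is.na(got)))
  rep <- attr(got, "report")
  expect_setequal(rep$verbatim, c("soon", "999", "12345", "3020"))
})

test_that("empty input yields no year and no report rows", {
  got <- standardize_event_date(c(NA, ""))
  expect_true(all(is.na(got)))
  expect_equal(nrow(attr(got, "report")), 0)
})
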