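empty_records <- function() {
  tibble::tibble(location = character(0), locationID = integer(0),
                 taxon = character(0), taxonID = integer(0),
                 eventDate = integer(0), habitat = character(0),
                 occurrenceStatus = character(0), establishmentMeans = character(0),
                 degreeOfEstablishment = character(0), pathway = character(0),
                 datasetName = character(0), bibliographicCitation = character(0))
}

empty_taxa <- function() {
  tibble::tibble(scientificName = character(0), verbatimTaxonRank = character(0),
                 taxon = character(0), GBIFstatus = character(0),
                 GBIFstatus_Synonym = character(0), GBIFmatchtype = character(0),
                 GBIFtaxonRank = character(0), GBIFusageKey = integer(0),
                 GBIFnote = character(0), species = character(0),
                 genus = character(0), family = character(0), order = character(0),
                 class = character(0), phylum = character(0), kingdom = character(0),
                 taxonID = integer(0), taxaGroup = character(0))
}

test_that("empty tables validate vacuously", {
  expect_equal(nrow(validate_output_tables(empty_records(), empty_taxa())), 0)
})

test_that("a pathway on a native record violates the introduced-only rule", {
  rec <- dplyr::add_row(empty_records(), location = "Aland", locationID = 58L,
                        taxon = "X x", taxonID = 1L,
                        establishmentMeans = "native", pathway = "corridor",
                        datasetName = "S1", bibliographicCitation = "Cite")
  taxa <- dplyr::add_row(empty_taxa(), verbatimTaxonRank = "X x", taxon = "X x",
                         GBIFstatus = "MISSING", taxonID = 1L)
  v <- validate_output_tables(rec, taxa)
  expect_true("introduced-only" %in% v$rule)
})

test_that("duplicate record keys, stray backbone fields and broken pairings are caught", {
  taxa <- dplyr::add_row(empty_taxa(), verbatimTaxonRank = "X x", taxon = "X x",
                         GBIFstatus = "MISSING", taxonID = 1L, kingdom = "Animalia")
  rec <- dplyr::bind_rows(
    dplyr::add_row(empty_records(), location = "Aland", locationID = 58L,
                   taxon = "X x", taxonID = 1L, establishmentMeans = "native",
                   datasetName = "S1", bibliographicCitation = "C"),
    dplyr::add_row(empty_records(), location = "Aland", locationID = 58L,
                   taxon = "X x", taxonID = 1L, establishmentMeans = "native",
                   datasetName = "S1", bibliographicCitation = "C"),
    dplyr::add_row(empty_records(), location = "Aland", locationID = 58L,
                   taxon = "Wrong name", taxonID = 1L, establishmentMeans = "vagrant",
                   datasetName = "S1", bibliographicCitation = "C")
  )
  v <- validate_output_tables(rec, taxa)
  expect_true(all(c("unique-record-key", "missing-no-backbone",
                    "taxon-id-pairing") %in% v$rule))
})

test_that("a missing required column is a schema error naming the column", {
  rec <- empty_records()[, -2]
  expect_error(validate_output_tables(rec, empty_taxa()), "locationID",
               class = "aliendist_schema_error")
})

test_that("percentages use round-half-up at one decimal", {
  expect_equal(round_half_up(56.25, 1), 56.3)   # base round() would give 56.2
  expect_equal(round_half_up(1.05, 1), 1.1)
  expect_equal(percentage(1, 3), 33.3)
  expect_equal(percentage(0, 0), NA_real_)
  expect_equal(percentage(4, 10), 40.0)
})
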