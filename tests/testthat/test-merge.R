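std_row <- function(taxon, locID, em, src = "S1", occ = NA, deg = NA, pw = NA,
                    hab = NA, yr = NA) {
  tibble::tibble(source_name = src, taxon = taxon, location = "Aland",
                 locationID = locID, establishmentMeans = em,
                 occurrenceStatus = as.character(occ),
                 degreeOfEstablishment = as.character(deg),
                 pathway = as.character(pw), habitat = as.character(hab),
                 eventDate = as.integer(yr))
}

test_that("introduced and uncertain records concatenate; native stays separate", {
  rec <- dplyr::bind_rows(
    std_row("X x", 58L, "introduced", src = "A", yr = 1950),
    std_row("X x", 58L, "uncertain", src = "B"),
    std_row("Y y", 58L, "native", src = "A"),
    std_row("Y y", 58L, "introduced", src = "B")
  )
  out <- merge_records(rec, c(A = "Cite A", B = "Cite B"))
  x <- out[out$taxon == "X x", ]
  expect_equal(nrow(x), 1)
  expect_equal(x$establishmentMeans, "introduced; uncertain")
  expect_equal(x$eventDate, 1950L)
  expect_equal(x$datasetName, "A; B")
  expect_equal(x$bibliographicCitation, "Cite A; Cite B")
  y <- out[out$taxon == "Y y", ]
  expect_equal(nrow(y), 2)
  expect_setequal(y$establishmentMeans, c("native", "introduced"))
})

test_that("duplicates merge keeping the earliest first record", {
  rec <- dplyr::bind_rows(
    std_row("X x", 58L, "introduced", yr = 1950),
    std_row("X x", 58L, "introduced", yr = 1903, src = "S2")
  )
  out <- merge_records(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$eventDate, 1903L)
})

test_that("present beats absent on conflict and the disagreement is logged", {
  rec <- dplyr::bind_rows(
    std_row("X x", 58L, "introduced", occ = "absent"),
    std_row("X x", 58L, "introduced", occ = "present", src = "S2")
  )
  out <- merge_records(rec)
  expect_equal(out$occurrenceStatus, "present")
  expect_equal(nrow(attr(out, "status_conflicts")), 1)
})

test_that("degree and pathway attach only to records starting with introduced", {
  rec <- dplyr::bind_rows(
    std_row("U u", 58L, "uncertain", deg = "established", pw = "corridor"),
    std_row("V v", 58L, "vagrant"),
    std_row("W w", 58L, "introduced", deg = "established", pw = "corridor"),
    std_row("W w", 58L, "introduced", deg = "invasive", pw = "unaided", src = "S2")
  )
  out <- merge_records(rec)
  u <- out[out$taxon == "U u", ]
  expect_equal(u$establishmentMeans, "uncertain")
  expect_true(is.na(u$degreeOfEstablishment) && is.na(u$pathway))
  w <- out[out$taxon == "W w", ]
  expect_equal(w$degreeOfEstablishment, "invasive")   # most advanced stage
  expect_equal(w$pathway, "corridor; unaided")        # sorted union
  expect_true(all(is.na(out$pathway[out$establishmentMeans %in%
                                      c("native", "vagrant", "uncertain")])))
})

test_that("habitat attaches to the taxon across all its records", {
  rec <- dplyr::bind_rows(
    std_row("X x", 58L, "introduced", hab = "marine"),
    std_row("X x", 12L, "native", hab = "brackish; marine")
  )
  out <- merge_records(rec)
  expect_equal(unique(out$habitat), "brackish; marine")
})

test_that("unmatched locations and missing establishment go to the exclusion report", {
  rec <- dplyr::bind_rows(
    std_row("X x", NA, "introduced"),
    std_row("Y y", 58L, NA),
    std_row("Z z", 58L, "native")
  )
  out <- merge_records(rec)
  excl <- attr(out, "exclusions")
  expect_equal(nrow(out), 1)
  expect_equal(nrow(excl), 2)
  expect_setequal(excl$reason, c("unmatched location", "missing establishmentMeans"))
  # count conservation: every input record lands in a merge group or exclusion
  expect_equal(sum(!is.na(rec$locationID) & !is.na(rec$establishmentMeans)) +
                 nrow(excl), nrow(rec))
})

test_that("merging is idempotent and order-invariant", {
  rec <- random_std_records(120, seed = 5)
  out <- merge_records(rec, fixture_citations)
  again <- merge_records(
    out |> dplyr::mutate(source_name = datasetName) |>
      tidyr::separate_rows("source_name", sep = "; "),
    setNames(fixture_citations[c("S1", "S2", "S3")], c("S1", "S2", "S3")))
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
  perm <- rec[withr::with_seed(9, sample(nrow(rec))), ]
  expect_equal(as.data.frame(merge_records(perm, fixture_citations)),
               as.data.frame(out), ignore_attr = TRUE)
})

test_that("the vectorized merge equals the naive reference on random tables", {
  for (seed in 1:15) {
    rec <- random_std_records(sample(20:200, 1), seed = seed)
    a <- merge_records(rec, fixture_citations)
    b <- merge_records_naive(rec, fixture_citations)
    expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE,
                 info = paste("seed", seed))
  }
})

test_that("identifiers are stable: locationIDs from the table, taxonIDs lexicographic", {
  taxa <- tibble::tibble(
    scientificName = NA_character_,
    verbatimTaxonRank = c("B syn", "A a", "B b"),
    taxon = c("B b", "A a", "B b"),
    GBIFstatus = c("SYNONYM", "ACCEPTED", "ACCEPTED"),
    GBIFstatus_Synonym = NA, GBIFmatchtype = "EXACT", GBIFtaxonRank = "SPECIES",
    GBIFusageKey = NA_integer_, GBIFnote = NA_character_,
    species = NA, genus = NA, family = NA, order = NA, class = NA,
    phylum = NA, kingdom = NA, taxaGroup = NA_character_
  )
  rec <- merge_records(dplyr::bind_rows(std_row("A a", 58L, "native"),
                                        std_row("B b", 58L, "introduced")))
  ids <- assign_ids(rec, taxa)
  expect_equal(ids$taxa$taxonID, 1:3)
  expect_equal(ids$taxa$verbatimTaxonRank, c("A a", "B b", "B syn"))
  # records take the taxonID of the first taxa entry for their accepted name
  expect_equal(ids$records$taxonID[ids$records$taxon == "B b"], 2L)
  expect_equal(ids$records$locationID, c(58L, 58L))
  # appending a lexicographically last taxon leaves earlier IDs unchanged
  taxa2 <- dplyr::add_row(taxa, verbatimTaxonRank = "Z z", taxon = "Z z",
                          GBIFstatus = "MISSING")
  ids2 <- assign_ids(rec, taxa2)
  expect_equal(ids2$taxa$taxonID[match(taxa$verbatimTaxonRank, ids2$taxa$verbatimTaxonRank)],
               ids$taxa$taxonID[match(taxa$verbatimTaxonRank, ids$taxa$verbatimTaxonRank)])
})

test_that("dataset summaries count and percentage correctly", {
  rec <- dplyr::bind_rows(
    lapply(1:4, function(i) std_row(paste("T", i), 58L, "introduced")),
    lapply(5:10, function(i) std_row(paste("T", i), 58L, "native"))
  )
  merged <- merge_records(rec)
  taxa <- build_taxa_list(dplyr::bind_rows(lapply(unique(rec$taxon), aliendist:::empty_match)))
  ids <- assign_ids(merged, taxa)
  s <- summarize_dataset(ids$records, ids$taxa)
  expect_equal(s$stats$n_records, 10)
  expect_equal(s$stats$pct_introduced, 40.0)
  expect_equal(s$stats$pct_native, 60.0)
  expect_equal(s$stats$n_taxa_matched_backbone, 0)
  # empty dataset: zero counts, undefined percentages reported as NA
  s0 <- summarize_dataset(ids$records[0, ], ids$taxa[0, ])
  expect_equal(s0$stats$n_records, 0)
  expect_true(is.na(s0$stats$pct_introduced))
})
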