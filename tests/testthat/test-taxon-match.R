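test_that("an exact accepted name matches as ACCEPTED/EXACT with higher taxonomy", {
  bb <- make_backbone(bb_row(1L, "Avus primus"))
  m <- match_taxon("Avus primus", bb)
  expect_equal(m$status, "ACCEPTED")
  expect_equal(m$match_type, "EXACT")
  expect_equal(m$taxon, "Avus primus")
  expect_equal(m$usage_key, 1L)
  expect_equal(m$class, "Aves")
  expect_equal(m$taxa_group, "Birds")
})

test_that("synonyms resolve to the accepted name and converge", {
  bb <- make_backbone(
    bb_row(1L, "Avus primus"),
    bb_row(2L, "Avus vetus", status = "SYNONYM", accepted = 1L)
  )
  m <- match_taxon("Avus vetus", bb)
  expect_equal(m$status, "SYNONYM")
  expect_equal(m$status_synonym, "ACCEPTED")
  expect_equal(m$taxon, "Avus primus")       # replaced by accepted name
  expect_equal(m$usage_key, 1L)
  expect_equal(m$note, "Accepted name found on GBIF")
})

test_that("a synonym pointing at several accepted names is flagged", {
  bb <- make_backbone(
    bb_row(1L, "Avus primus"),
    bb_row(2L, "Avus alter"),
    bb_row(3L, "Avus vetus", status = "SYNONYM", accepted = 1L),
    bb_row(4L, "Avus vetus", status = "SYNONYM", accepted = 2L,
           author = "Other, 1910")
  )
  # two exact synonym hits: homonym resolution fails without hints
  m <- match_taxon("Avus vetus", bb)
  expect_equal(m$status, "MISSING")
  expect_equal(m$note, "Homonym in GBIF")
})

test_that("fuzzy matching accepts a sole candidate only at confidence 100", {
  bb1 <- make_backbone(bb_row(1L, "Avus primus"))
  m <- match_taxon("Avus primqs", bb1)       # one edit away, unique
  expect_equal(m$status, "ACCEPTED")
  expect_equal(m$match_type, "FUZZY")
  expect_equal(m$taxon, "Avus primus")

  # a second name within distance 2 of the query drops confidence below 100
  bb2 <- make_backbone(bb_row(1L, "Avus primus"), bb_row(2L, "Avus primas"))
  fz <- lookup_fuzzy(bb2, "Avus primqs")
  expect_true(all(fz$confidence < 100))
  m2 <- match_taxon("Avus primqs", bb2)
  expect_equal(m2$status, "MISSING")
  expect_equal(m2$taxon, "Avus primqs")      # unmatched names are kept verbatim
})

test_that("whenever an exact match exists no fuzzy result is used", {
  # the exact name is one edit from a different accepted name: exact wins
  bb <- make_backbone(bb_row(1L, "Avus primus"), bb_row(2L, "Avus primux", author = "B, 1901"))
  m <- match_taxon("Avus primux", bb)
  expect_equal(m$usage_key, 2L)
  expect_equal(m$match_type, "EXACT")
})

test_that("homonyms resolve through author, kingdom and group hints in order", {
  cands <- dplyr::bind_rows(
    bb_row(1L, "Dupla nomen", author = "Smith, 1900", kingdom = "Animalia",
           phylum = "Chordata", class = "Aves"),
    bb_row(2L, "Dupla nomen", author = "Jones, 1950", kingdom = "Plantae",
           phylum = "Tracheophyta", class = "Magnoliopsida")
  )
  expect_equal(resolve_homonym(cands, list(kingdom = "Plantae"))$usage_key, 2L)
  expect_equal(resolve_homonym(cands, list(author = "Smith, 1900"))$usage_key, 1L)
  expect_equal(resolve_homonym(cands, list(group = "Vascular plants"))$usage_key, 2L)
  expect_null(resolve_homonym(cands, list()))
  expect_null(resolve_homonym(cands, list(kingdom = "Fungi")))  # discards all

  three <- dplyr::bind_rows(cands, bb_row(3L, "Dupla nomen", author = "Lee, 1980",
                                          kingdom = "Animalia", class = "Insecta",
                                          phylum = "Arthropoda"))
  expect_equal(resolve_homonym(three, list(author = "Lee, 1980"))$usage_key, 3L)

  bb <- make_backbone(cands)
  m <- match_taxon("Dupla nomen", bb, hints = list(kingdom = "Plantae"))
  expect_equal(m$taxa_group, "Vascular plants")
  m2 <- match_taxon("Dupla nomen", bb)
  expect_equal(m2$status, "MISSING")
  expect_equal(m2$note, "Homonym in GBIF")
  expect_true(is.na(m2$usage_key) && is.na(m2$kingdom) && is.na(m2$taxa_group))
})

test_that("authority and date strip off while infraspecific markers survive", {
  expect_equal(strip_authority("Lonchura malacca (Linnaeus, 1766)"), "Lonchura malacca")
  expect_equal(strip_authority("Lonchura malacca"), "Lonchura malacca")
  expect_equal(strip_authority("Abies alba Mill."), "Abies alba")
  expect_equal(strip_authority("Poa annua var. supina Schrad."), "Poa annua var. supina")
  bb <- make_backbone(bb_row(1L, "Abies alba", author = "Mill."))
  expect_equal(strip_authority(bb$table$scientific_name[1]), bb$table$canonical_name[1])
})

test_that("taxa groups follow the first matching ordered rule", {
  higher <- list(species = NA, genus = NA, family = NA, order = NA,
                 class = "Aves", phylum = "Chordata", kingdom = "Animalia")
  expect_equal(assign_taxa_group(higher), "Birds")
  higher$class <- "Insecta"; higher$phylum <- "Arthropoda"
  expect_equal(assign_taxa_group(higher), "Insects")
  higher$class <- "Diplopoda"  # no class rule: falls through to phylum
  expect_equal(assign_taxa_group(higher), "Other arthropods")
  expect_equal(assign_taxa_group(list(kingdom = "Fungi")), "Fungi")
  expect_true(is.na(assign_taxa_group(list(kingdom = NA))))
  expect_error(assign_taxa_group(higher, tibble::tibble(rank = "tribe", value = "x",
                                                        group = "y")),
               class = "aliendist_config_error")
  # shipped rules cover exactly the 20 documented labels
  expect_equal(dplyr::n_distinct(default_taxa_group_rules()$group), 20)
})

test_that("the taxa table keeps original names and shares accepted names across synonyms", {
  bb <- make_backbone(
    bb_row(1L, "Avus primus"),
    bb_row(2L, "Avus vetus", status = "SYNONYM", accepted = 1L)
  )
  rec <- raw_records("S1", c("Avus primus", "Avus vetus", "Ghostus absentis"), "X")
  matches <- match_taxa(rec, bb)
  taxa <- build_taxa_list(matches)
  expect_equal(nrow(taxa), 3)
  syn_pair <- taxa[taxa$taxon == "Avus primus", ]
  expect_equal(nrow(syn_pair), 2)
  expect_setequal(syn_pair$verbatimTaxonRank, c("Avus primus", "Avus vetus"))
  ghost <- taxa[taxa$verbatimTaxonRank == "Ghostus absentis", ]
  expect_equal(ghost$GBIFstatus, "MISSING")
  expect_true(is.na(ghost$kingdom) && is.na(ghost$GBIFusageKey))
  expect_equal(build_taxa_list(matches[0, ]) |> nrow(), 0)
})

test_that("matching agrees with a brute-force backbone scan and ignores record order", {
  fx <- generate_backbone(fixture_spec(seed = 31, n_true_taxa = 30), withr::local_tempdir())
  bb <- local_backbone(fx$path)
  names <- fx$manifest$verbatim
  for (v in names) {
    got <- match_taxon(v, bb)
    want <- oracle_match_scan(v, fx$table)
    if (want$outcome == "HOMONYM") {
      expect_equal(got$status, "MISSING", info = v)
      expect_equal(got$note, "Homonym in GBIF", info = v)
    } else {
      expect_equal(got$status, want$outcome, info = v)
      expect_equal(got$taxon, want$taxon, info = v)
    }
  }
  rec <- raw_records("S1", names, "X")
  perm <- rec[rev(seq_len(nrow(rec))), ]
  expect_equal(match_taxa(rec, bb), match_taxa(perm, bb))
})
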