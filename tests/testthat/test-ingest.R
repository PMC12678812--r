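write_src <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "src.csv")
  readr::write_csv(df, p, na = "")
  p
}

base_cfg <- function(..., column_map = list(taxon = "sp", location = "loc"),
                     scope = "alien") {
  source_config(source_name = "SRC", citation = "Cite (2024)",
                scope = scope, column_map = column_map, ...)
}

test_that("a plain file loads with verbatim values preserved", {
  p <- write_src(tibble::tibble(sp = c("A a", "B b", "C c"),
                                loc = c("X", "Y", "Z"),
                                status = c("native", "alien", "")))
  cfg <- base_cfg(scope = "mixed",
                  column_map = list(taxon = "sp", location = "loc",
                                    establishment = "status"))
  rec <- load_source(p, cfg)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$taxon_verbatim, c("A a", "B b", "C c"))
  expect_equal(rec$establishment_verbatim, c("native", "alien", NA))
})

test_that("rows with empty taxon or location are dropped and counted", {
  p <- write_src(tibble::tibble(sp = c("A a", "", "C c"), loc = c("X", "Y", "")))
  rec <- load_source(p, base_cfg(scope = "alien"))
  expect_equal(nrow(rec), 1)
  log <- attr(rec, "ingest_log")
  expect_equal(log$n[log$reason == "empty_taxon"], 1L)
  expect_equal(log$n[log$reason == "empty_location"], 1L)
})

test_that("a mapped column missing from the file names the source and column", {
  p <- write_src(tibble::tibble(sp = "A a"))
  expect_error(load_source(p, base_cfg()), "SRC.*loc", class = "aliendist_config_error")
})

test_that("keep and drop rules filter as configured and are idempotent", {
  df <- tibble::tibble(sp = paste("T", 1:4), loc = "X",
                       flag = c("established outdoors", "indoors only",
                                "established outdoors", "eradicated"),
                       doubt = c("0", "0", "1", "0"))
  cfg <- base_cfg(scope = "alien",
                  keep_rules = list(flag = list("established outdoors")),
                  drop_rules = list(doubt = list("1")))
  once <- apply_source_filters(df, cfg)
  expect_equal(once$sp, "T 1")
  expect_equal(apply_source_filters(once, cfg), once)
  # no rules: identity
  expect_equal(apply_source_filters(df, base_cfg()), df)
})

test_that("binary establishment codes decode; unknown codes stay verbatim and are logged", {
  rec <- raw_records("SRC", c("A a", "B b", "C c"), "X",
                     establishment_verbatim = c("1", "0", "2"))
  cfg <- base_cfg(establishment_encoding = c("1" = "native", "0" = "introduced"))
  out <- decode_establishment(rec, cfg)
  expect_equal(out$establishment_verbatim, c("native", "introduced", "2"))
  expect_equal(attr(out, "decode_log")$code, "2")
})

test_that("multiple location columns combine to the finest non-empty level", {
  df <- tibble::tibble(sp = c("A", "B", "C"),
                       island = c("Hawaii", "", ""),
                       country = c("United States", "Colombia", ""))
  cfg <- base_cfg(scope = "alien",
                  column_map = list(taxon = "sp", location = list("island", "country")))
  expect_equal(combine_location_columns(df, cfg), c("Hawaii", "Colombia", NA))
  p <- write_src(df |> dplyr::rename(loc = "island"))  # unused; just file shape
  p2 <- file.path(dirname(p), "mc.csv"); readr::write_csv(df, p2, na = "")
  rec <- load_source(p2, cfg)
  expect_equal(rec$location_verbatim, c("Hawaii", "Colombia"))
  expect_equal(attr(rec, "ingest_log")$n[attr(rec, "ingest_log")$reason == "empty_location"], 1L)
})

test_that("single-scope sources inherit the scope establishment value", {
  p <- write_src(tibble::tibble(sp = c("A a", "B b"), loc = "X"))
  alien <- load_source(p, base_cfg(scope = "alien"))
  expect_true(all(alien$establishment_verbatim == "introduced"))
  native <- load_source(p, base_cfg(scope = "native"))
  expect_true(all(native$establishment_verbatim == "native"))
  # a mixed-scope source must map an establishment column
  expect_error(base_cfg(scope = "mixed"), class = "aliendist_config_error")
})

test_that("a restriction list keeps only listed taxa (normalized comparison)", {
  dir <- withr::local_tempdir()
  lp <- file.path(dir, "list.txt")
  writeLines(c("  a A ", "B b"), lp)
  p <- file.path(dir, "src.csv")
  readr::write_csv(tibble::tibble(sp = c("A a", "B b", "C c"), loc = "X"), p)
  cfg <- base_cfg(scope = "alien", restrict_to_list = lp)
  rec <- load_source(p, cfg)
  expect_setequal(rec$taxon_verbatim, c("A a", "B b"))
  log <- attr(rec, "ingest_log")
  expect_equal(log$n[log$reason == "not_on_restriction_list"], 1L)
})
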