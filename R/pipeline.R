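# Orchestration: a full run from one configuration -- ingest, term /
# location / taxon / date standardization, merge, validation, output.

#' Standardize raw records
#'
#' Applies, per source: vocabulary translation of the status fields
#' (establishment, occurrence, degree of establishment, pathway), habitat
#' categorization, first-record date normalization, and place-name
#' standardization against the location reference system. Verbatim values
#' that cannot be translated leave the field absent (for pathway and the
#' other optional fields the record survives; a record without a matched
#' location or establishment value is excluded later, at merge).
#'
#' @param raw raw-record tibble (possibly several sources).
#' @param vocabs named list of vocabularies ([default_vocabularies()]).
#' @param locations a `location_table`.
#' @param date_bounds plausibility window for years.
#' @return list: `records` (standardized tibble), `term_reports` (named
#'   list of per-field match/unmatch tibbles), `unmatched_locations`.
#' @export
standardize_records <- function(raw, vocabs = default_vocabularies(), locations,
                                date_bounds = c(1000L, as.integer(format(Sys.Date(), "%Y")))) {
  pieces <- split(raw, raw$source_name)
  reports <- list(establishmentMeans = list(), occurrenceStatus = list(),
                  degreeOfEstablishment = list(), pathway = list(),
                  habitat = list(), eventDate = list())
  out <- purrr::map(pieces, function(p) {
    src <- p$source_name[1]
    em <- standardize_term(p$establishment_verbatim, vocabs$establishmentMeans, src)
    oc <- standardize_term(p$occurrence_verbatim, vocabs$occurrenceStatus, src)
    dg <- standardize_term(p$degree_verbatim, vocabs$degreeOfEstablishment, src)
    pw <- standardize_term(p$pathway_verbatim, vocabs$pathway, src)
    hb <- standardize_habitat(p$habitat_verbatim, vocabs$habitat, source_name = src)
    yr <- standardize_event_date(p$event_date_verbatim, bounds = date_bounds,
                                 source_name = src)
    for (f in c("establishmentMeans", "occurrenceStatus", "degreeOfEstablishment",
                "pathway", "habitat", "eventDate")) {
      r <- switch(f, establishmentMeans = attr(em, "report"),
                  occurrenceStatus = attr(oc, "report"),
                  degreeOfEstablishment = attr(dg, "report"),
                  pathway = attr(pw, "report"), habitat = attr(hb, "report"),
                  eventDate = attr(yr, "report"))
      reports[[f]][[src]] <<- r
    }
    loc <- standardize_location(p$location_verbatim, locations)
    tibble::tibble(
      source_name = src,
      taxon_verbatim = p$taxon_verbatim,
      location_verbatim = p$location_verbatim,
      location = loc$location, locationID = loc$locationID,
      establishmentMeans = as.character(em), occurrenceStatus = as.character(oc),
      degreeOfEstablishment = as.character(dg), pathway = as.character(pw),
      habitat = as.character(hb), eventDate = as.integer(yr),
      author_hint = p$author_hint, kingdom_hint = p$kingdom_hint,
      group_hint = p$group_hint
    )
  }) |> dplyr::bind_rows()

  term_reports <- purrr::map(reports, function(lst) {
    dplyr::bind_rows(lst) |>
      dplyr::arrange(.data$source_name, .data$verbatim)
  })
  unmatched_loc <- out |>
    dplyr::filter(is.na(.data$location)) |>
    dplyr::count(.data$source_name, .data$location_verbatim, name = "count") |>
    dplyr::rename(verbatim = "location_verbatim") |>
    dplyr::arrange(.data$source_name, .data$verbatim)
  list(records = out, term_reports = term_reports,
       unmatched_locations = unmatched_loc)
}

#' Build a run configuration
#'
#' @param sources path to the YAML source-configuration file (see
#'   [read_source_configs()]).
#' @param location_polygons,location_translation the location reference
#'   layer (WKT polygon table) and translation table.
#' @param backbone_mode `"local"` (table-backed fixture backbone) or
#'   `"gbif_cached"` (cache-backed live-service adapter).
#' @param backbone_path backbone table (local) or JSON-lines cache.
#' @param translation_dir optional directory of per-field translation
#'   tables; the shipped default vocabularies are used when absent.
#' @param taxa_group_rules optional path to a taxa-group rule table.
#' @param output_dir optional output directory; no files are written when
#'   `NULL`.
#' @param stages stage toggles, currently `taxon_matching` (disabling it
#'   leaves every taxon unmatched / `MISSING`).
#' @param options numeric options: `min_overlap_fraction` for range-map
#'   overlay, `date_bounds`, `offline` for the cached adapter.
#' @return a validated `run_config` object.
#' @export
run_config <- function(sources, location_polygons, location_translation,
                       backbone_mode = c("local", "gbif_cached"),
                       backbone_path, translation_dir = NULL,
                       taxa_group_rules = NULL, output_dir = NULL,
                       stages = list(taxon_matching = TRUE),
                       options = list()) {
  cfg <- structure(list(
    sources = sources, location_polygons = location_polygons,
    location_translation = location_translation,
    backbone_mode = match.arg(backbone_mode), backbone_path = backbone_path,
    translation_dir = translation_dir, taxa_group_rules = taxa_group_rules,
    output_dir = output_dir,
    stages = modifyList(list(taxon_matching = TRUE), stages),
    options = modifyList(list(min_overlap_fraction = 0,
                              date_bounds = c(1000L, as.integer(format(Sys.Date(), "%Y"))),
                              offline = TRUE), options)
  ), class = "run_config")
  cfg$options$date_bounds <- as.integer(unlist(cfg$options$date_bounds))
  cfg$options$min_overlap_fraction <- as.numeric(cfg$options$min_overlap_fraction)
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#' @param config a `run_config`.
#' @return the config, invisibly; aborts with config diagnostics otherwise.
#' @export
validate_run_config <- function(config) {
  need <- c(config$sources, config$location_polygons, config$location_translation,
            config$backbone_path, config$translation_dir, config$taxa_group_rules)
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    abort_config(paste("run config: missing input path(s):",
                       paste(missing, collapse = ", ")))
  }
  if (!config$backbone_mode %in% c("local", "gbif_cached")) {
    abort_config("run config: backbone_mode must be 'local' or 'gbif_cached'")
  }
  invisible(config)
}

#' Read a run configuration from YAML
#' @param path YAML file; relative paths are resolved against its
#'   directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("run config not found: %s", path))
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  run_config(
    sources = rel(y$sources),
    location_polygons = rel(y$locations$polygons),
    location_translation = rel(y$locations$translation),
    backbone_mode = y$backbone$mode %||% "local",
    backbone_path = rel(y$backbone$path),
    translation_dir = rel(y$translation_tables),
    taxa_group_rules = rel(y$taxa_group_rules),
    output_dir = rel(y$output_dir),
    stages = y$stages %||% list(),
    options = y$options %||% list()
  )
}

#' Run the full harmonization pipeline
#'
#' Executes ingest (checklists and range-map overlay), standardization
#' (terms, habitat, dates, locations), taxonomic matching, merging,
#' identifier assignment, validation, and -- when an output directory is
#' configured -- file output. The run manifest records a configuration
#' hash and per-stage record counts.
#'
#' @param config a `run_config` (or path to a YAML run configuration).
#' @return a `harmonization_run`: list with `records`, `taxa`, `reports`,
#'   `summary`, `validation`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  t0 <- Sys.time()
  counts <- list()

  src_cfgs <- read_source_configs(config$sources)
  locations <- load_locations(config$location_polygons, config$location_translation)
  vocabs <- if (is.null(config$translation_dir)) default_vocabularies() else {
    vv <- list()
    for (f in VOCAB_FIELDS) {
      p <- file.path(config$translation_dir, paste0(f, ".csv"))
      vv[[f]] <- if (file.exists(p)) read_translation_table(p, f) else
        default_vocabularies()[[f]]
    }
    vv
  }
  group_rules <- if (is.null(config$taxa_group_rules)) default_taxa_group_rules()
    else read_taxa_group_rules(config$taxa_group_rules)
  backbone <- if (config$backbone_mode == "local") local_backbone(config$backbone_path)
    else gbif_backbone(config$backbone_path, offline = isTRUE(config$options$offline))

  ingest_logs <- list(); raw_list <- list()
  for (nm in names(src_cfgs)) {
    sc <- src_cfgs[[nm]]
    if (identical(sc$type, "range_map")) {
      feats <- readr::read_csv(sc$path, col_types = readr::cols(.default = "c"),
                               progress = FALSE, show_col_types = FALSE)
      feats$source_name <- sc$source_name
      rec <- overlay_range_maps(feats, locations,
                                origin_keep = sc$origin_keep,
                                min_fraction = config$options$min_overlap_fraction)
    } else {
      rec <- load_source(sc$path, sc)
      ingest_logs[[nm]] <- attr(rec, "ingest_log")
    }
    raw_list[[nm]] <- rec
  }
  raw <- dplyr::bind_rows(raw_list)
  counts$ingested <- nrow(raw)

  std <- standardize_records(raw, vocabs, locations,
                             date_bounds = config$options$date_bounds)
  counts$standardized <- nrow(std$records)

  if (isTRUE(config$stages$taxon_matching)) {
    matches <- match_taxa(std$records, backbone, group_rules)
  } else {
    nm <- sort(unique(std$records$taxon_verbatim))
    matches <- dplyr::bind_rows(purrr::map(nm, empty_match))
  }
  taxa <- build_taxa_list(matches)
  counts$taxa <- nrow(taxa)

  std_rec <- std$records |>
    dplyr::mutate(taxon = matches$taxon[match(.data$taxon_verbatim,
                                              matches$verbatim_name)])
  citations <- vapply(src_cfgs, function(s) s$citation, character(1))
  names(citations) <- vapply(src_cfgs, function(s) s$source_name, character(1))
  merged <- merge_records(std_rec, citations)
  counts$merged <- nrow(merged)
  counts$excluded <- nrow(attr(merged, "exclusions"))

  ids <- assign_ids(merged, taxa)
  validation <- validate_output_tables(ids$records, ids$taxa)
  summary <- summarize_dataset(ids$records, ids$taxa)

  exclusions <- attr(merged, "exclusions") |>
    dplyr::count(.data$source_name,
                 verbatim = .data$taxon_verbatim, .data$reason, name = "count") |>
    dplyr::mutate(field = "record", .before = "verbatim") |>
    dplyr::arrange(.data$source_name, .data$verbatim)
  reports <- list(
    term_reports = std$term_reports,
    unmatched_locations = std$unmatched_locations,
    exclusions = exclusions,
    ingest_log = dplyr::bind_rows(ingest_logs),
    status_conflicts = attr(merged, "status_conflicts")
  )

  written <- character(0)
  if (!is.null(config$output_dir)) {
    if (nrow(validation)) {
      rlang::abort("validation failed; outputs not written (see $validation)",
                   class = "aliendist_validation_error")
    }
    written <- write_outputs(ids$records, ids$taxa, reports, config$output_dir)
  }

  manifest <- tibble::tibble(
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    stage = names(counts), n = unlist(counts, use.names = FALSE),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(records = ids$records, taxa = ids$taxa, reports = reports,
                 summary = summary, validation = validation, manifest = manifest,
                 written = written, config = config),
            class = "harmonization_run")
}

#' @export
print.harmonization_run <- function(x, ...) {
  cat(sprintf("<harmonization_run: %d records, %d taxa, %d validation issue(s)>\n",
              nrow(x$records), nrow(x$taxa), nrow(x$validation)))
  invisible(x)
}

#' Tidy a harmonization run
#' @param x a `harmonization_run`.
#' @param table `"records"` (default) or `"taxa"`.
#' @param ... unused.
#' @return the requested output table as a tibble.
#' @export
tidy.harmonization_run <- function(x, table = c("records", "taxa"), ...) {
  table <- match.arg(table)
  tibble::as_tibble(x[[table]])
}

#' One-row summary of a harmonization run
#' @param x a `harmonization_run`.
#' @param ... unused.
#' @return one-row tibble of dataset-level counts and percentages.
#' @export
glance.harmonization_run <- function(x, ...) x$summary$stats

#' Plot the composition of a harmonization run
#'
#' Bar chart of record counts by establishment means, or of taxon counts
#' by taxa group.
#'
#' @param object a `harmonization_run`.
#' @param type `"establishment"` (default) or `"taxa_group"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.harmonization_run <- function(object, type = c("establishment", "taxa_group"), ...) {
  type <- match.arg(type)
  if (type == "establishment") {
    df <- object$summary$by_establishment |>
      dplyr::filter(!is.na(.data$establishmentMeans))
    ggplot2::ggplot(df, ggplot2::aes(
      x = stats::reorder(.data$establishmentMeans, .data$n_records),
      y = .data$n_records)) +
      ggplot2::geom_col(fill = "#2c7fb8") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "records",
                    title = "Records by means of establishment")
  } else {
    df <- object$summary$by_taxa_group
    ggplot2::ggplot(df, ggplot2::aes(
      x = stats::reorder(.data$taxaGroup, .data$n_taxa), y = .data$n_taxa)) +
      ggplot2::geom_col(fill = "#31a354") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "taxa", title = "Taxa by group")
  }
}

#' Summarize written pipeline outputs
#'
#' Reads the two main tables back from an output directory and recomputes
#' the dataset summary -- the shell-facing counterpart of
#' [summarize_dataset()].
#'
#' @param dir output directory of a previous run.
#' @param records_file,taxa_file main output filenames.
#' @return a `dataset_summary`.
#' @export
summarize_outputs <- function(dir, records_file = "aliendist_records.csv",
                              taxa_file = "aliendist_taxa.csv") {
  rp <- file.path(dir, records_file); tp <- file.path(dir, taxa_file)
  if (!file.exists(rp) || !file.exists(tp)) {
    abort_config(sprintf("missing outputs under %s", dir))
  }
  summarize_dataset(read_output_table(rp), read_output_table(tp))
}
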