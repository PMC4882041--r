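#' Read a CSV dialect configuration
#'
#' A dialect maps source column names onto the canonical schema and recodes
#' free-text category labels onto the controlled vocabularies. The packaged
#' default mirrors the layout written by [generate_fixture_csv()].
#'
#' @param path Path to a YAML dialect file. `NULL` uses the packaged default.
#' @return A list with elements `name`, `delimiter`, `columns`, `recodes`.
#' @export
read_dialect <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "s1_dialect.yaml", package = "phycomacro")
  }
  stopifnot(file.exists(path))
  d <- yaml::read_yaml(path)
  d$delimiter <- d$delimiter %||% ","
  d$recodes <- d$recodes %||% list()
  stopifnot(is.list(d$columns), length(d$columns) > 0)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate the curated macromolecular database
#'
#' Looks for the full literature-compiled observation database, first at
#' `options(phycomacro.database = ...)`, then in the package's `extdata`
#' directory. The file is distributed separately from the package; an empty
#' string is returned when it is not installed.
#'
#' @param filename File name of the database CSV.
#' @return A path, or `""` when the database is not available.
#' @export
macrodb_path <- function(filename = "mm-public-database-phylum-level-v1.csv") {
  opt <- getOption("phycomacro.database", NULL)
  if (!is.null(opt) && nzchar(opt) && file.exists(opt)) return(opt)
  system.file("extdata", filename, package = "phycomacro")
}

.recode_values <- function(x, recodes, allowed, unknown_ok = TRUE) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "unknown"
  if (length(recodes)) {
    hit <- match(x, tolower(names(recodes)))
    x[!is.na(hit)] <- unlist(recodes, use.names = FALSE)[hit[!is.na(hit)]]
  }
  if (unknown_ok) x[!(x %in% allowed)] <- "unknown"
  x
}

#' Read, validate and deduplicate a macromolecular observation database
#'
#' Reads a delimited text file, applies the dialect's column mapping and
#' value recodes, and enforces the row-level invariants of the canonical
#' schema: phylum within the closed vocabulary, nonnegative values, percent
#' dry weight values at most 100, and a protein method recorded exactly for
#' protein rows. Rows failing an invariant are rejected (with a reason), not
#' fatal; missing mandatory columns are fatal. Exact duplicates on the
#' (study, species, condition, pool, basis, value, replicate) key are dropped
#' keeping the first occurrence and counted as rejections.
#'
#' @param path Path to the CSV file.
#' @param dialect A dialect list from [read_dialect()], or `NULL` for the
#'   packaged default.
#' @return A list with `table` (a validated observation tibble) and
#'   `report` (a validation report; see [validation_report_json()]).
#' @export
read_database <- function(path, dialect = NULL) {
  stopifnot(file.exists(path))
  if (is.null(dialect)) dialect <- read_dialect()
  raw <- readr::read_delim(
    path, delim = dialect$delimiter, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- trimws(names(raw))

  cols <- dialect$columns
  mandatory <- c("study_id", "phylum", "pool", "basis", "value")
  have <- vapply(cols, function(nm) nm %in% names(raw), logical(1))
  missing_mand <- intersect(mandatory, names(cols)[!have])
  # species identity: either a species_key column or genus+species
  has_key <- ("species_key" %in% names(cols) && isTRUE(have[["species_key"]])) ||
    all(c("genus", "species") %in% names(cols)[have])
  if (length(missing_mand) || !has_key) {
    need <- c(missing_mand, if (!has_key) "species_key (or genus+species)")
    stop("mandatory columns missing from ", path, ": ",
         paste(unlist(cols[missing_mand]), collapse = ", "),
         if (!has_key) " and no species identity columns (genus+species or species_key)")
  }

  pull <- function(field) {
    if (field %in% names(cols) && cols[[field]] %in% names(raw)) {
      raw[[cols[[field]]]]
    } else {
      rep(NA_character_, nrow(raw))
    }
  }

  genus <- pull("genus"); species <- pull("species"); strain <- pull("strain")
  species_key <- pull("species_key")
  no_key <- is.na(species_key) | species_key == ""
  composite <- trimws(paste(
    ifelse(is.na(genus), "", genus), ifelse(is.na(species), "", species),
    ifelse(is.na(strain), "", strain)
  ))
  species_key[no_key] <- gsub("\\s+", " ", composite[no_key])

  tbl <- tibble::tibble(
    row = seq_len(nrow(raw)),
    study_id = trimws(pull("study_id")),
    phylum = trimws(pull("phylum")),
    species_key = species_key,
    habitat = .recode_values(pull("habitat"), dialect$recodes$habitat, macro_habitats()),
    culture_system = .recode_values(pull("culture_system"), dialect$recodes$culture_system, macro_culture_systems()),
    growth_phase = .recode_values(pull("growth_phase"), dialect$recodes$growth_phase, macro_growth_phases()),
    nutrient_status = .recode_values(pull("nutrient_status"), dialect$recodes$nutrient_status, macro_nutrient_statuses()),
    pool = .recode_values(pull("pool"), dialect$recodes$pool, macro_pools(), unknown_ok = FALSE),
    basis = .recode_values(pull("basis"), dialect$recodes$basis, macro_bases(), unknown_ok = FALSE),
    value_chr = pull("value"),
    protein_method = .recode_values(pull("protein_method"), dialect$recodes$protein_method, macro_protein_methods(), unknown_ok = FALSE),
    replicate = pull("replicate")
  )
  tbl$value <- suppressWarnings(as.numeric(tbl$value_chr))
  # protein method is meaningful only for protein rows
  tbl$protein_method[tbl$pool != "protein"] <- "not_applicable"

  reason <- rep(NA_character_, nrow(tbl))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(tbl$study_id) | tbl$study_id == "", "missing study_id")
  flag(!(tbl$phylum %in% macro_phyla()), "unknown phylum")
  flag(is.na(tbl$species_key) | tbl$species_key == "", "missing species identity")
  flag(!(tbl$pool %in% macro_pools()), "unknown macromolecular pool")
  flag(!(tbl$basis %in% macro_bases()), "unknown basis")
  flag(is.na(tbl$value), "unparseable numeric value")
  flag(!is.na(tbl$value) & tbl$value < 0, "negative value")
  flag(!is.na(tbl$value) & tbl$basis == "percent_dry_weight" & tbl$value > 100,
       "percent dry weight above 100")
  flag(tbl$pool == "protein" & !(tbl$protein_method %in% c("peptide_or_amino_acid", "n_derived")),
       "protein row without a recognized protein method")

  ok <- is.na(reason)
  kept <- tbl[ok, , drop = FALSE]
  dup_key <- paste(kept$study_id, kept$species_key, kept$habitat,
                   kept$culture_system, kept$growth_phase, kept$nutrient_status,
                   kept$pool, kept$basis, kept$value, kept$replicate, sep = "\r")
  dup <- duplicated(dup_key)
  reason[kept$row[dup]] <- "duplicate row"
  kept <- kept[!dup, , drop = FALSE]

  out <- kept[, setdiff(.canonical_columns, character(0))]
  out <- structure(out, class = c("macro_obs", class(tibble::tibble())))
  attr(out, "provenance") <- list(path = normalizePath(path), loaded = Sys.time(),
                                  dialect = dialect$name %||% "unnamed")
  rejections <- tibble::tibble(row = tbl$row[!is.na(reason)],
                               reason = reason[!is.na(reason)])
  report <- structure(
    list(n_input = nrow(tbl), n_loaded = nrow(out),
         n_rejected = nrow(rejections), rejections = rejections,
         path = path),
    class = "macro_validation"
  )
  stopifnot(report$n_loaded + report$n_rejected == report$n_input)
  list(table = out, report = report)
}

#' @export
print.macro_validation <- function(x, ...) {
  cat("observation database validation:", x$path, "\n")
  cat("  rows in file :", x$n_input, "\n")
  cat("  rows loaded  :", x$n_loaded, "\n")
  cat("  rows rejected:", x$n_rejected, "\n")
  if (x$n_rejected > 0) {
    tab <- sort(table(x$rejections$reason), decreasing = TRUE)
    for (i in seq_along(tab)) cat("    -", names(tab)[i], ":", tab[i], "\n")
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A report from [read_database()].
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when written to a file.
#' @export
validation_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "macro_validation"))
  j <- jsonlite::toJSON(
    list(n_input = report$n_input, n_loaded = report$n_loaded,
         n_rejected = report$n_rejected,
         rejections = report$rejections),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' Filter observations to a growth regime
#'
#' `"active_growth"` keeps exponentially growing, nutrient-sufficient
#' cultures in batch, turbidostat or semi-continuous systems (chemostats,
#' whose steady states are set by the dilution rate, are excluded);
#' `"stationary"` keeps stationary-phase observations. Rows with unknown
#' growth phase or nutrient status match neither regime, since both regimes
#' are defined by positive criteria.
#'
#' @param table An observation tibble.
#' @param regime `"active_growth"` or `"stationary"`.
#' @return The filtered observation tibble (possibly empty).
#' @export
filter_condition <- function(table, regime = c("active_growth", "stationary")) {
  regime <- match.arg(regime)
  keep <- if (regime == "active_growth") {
    table$growth_phase == "exponential" &
      table$nutrient_status == "sufficient" &
      table$culture_system %in% c("batch", "turbidostat", "semi_continuous")
  } else {
    table$growth_phase == "stationary"
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(table, "provenance")
  attr(out, "regime") <- regime
  out
}

#' Split a table into phylum-comparison and pan-microalgae sets
#'
#' Euglenozoa and Rhodophyta carry too few observations for phylum-to-phylum
#' contrasts, so they are dropped from the comparison set while remaining in
#' the grand (pan-microalgae) pool.
#'
#' @param table An observation tibble, already filtered to one regime.
#' @return A list with `comparison` and `grand` observation tibbles.
#' @export
phylum_analysis_sets <- function(table) {
  comparison <- table[!(table$phylum %in% .excluded_comparison_phyla), , drop = FALSE]
  attr(comparison, "provenance") <- attr(table, "provenance")
  list(comparison = comparison, grand = table)
}

#' Tabulate observation counts by pool and basis
#'
#' @param table An observation tibble.
#' @return A tibble with columns `pool`, `basis`, `n`; totals equal
#'   `nrow(table)`.
#' @export
count_summary <- function(table) {
  if (nrow(table) == 0) {
    return(tibble::tibble(pool = character(), basis = character(), n = integer()))
  }
  dplyr::count(tibble::as_tibble(table), .data$pool, .data$basis, name = "n")
}
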