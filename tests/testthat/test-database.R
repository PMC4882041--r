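test_that("generated fixture CSVs round-trip through the loader with zero rejections", {
  d <- synthetic_design("tiny")
  g <- generate_dataset(d, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  generate_fixture_csv(g$table, path)
  res <- read_database(path)
  expect_equal(res$report$n_rejected, 0)
  expect_equal(res$report$n_loaded, nrow(g$table))
  expect_equal(nrow(g$table), 3 * 4 * 5 * length(d$pools))
  cs <- count_summary(res$table)
  expect_equal(sum(cs$n), nrow(res$table))
  expect_setequal(cs$pool, d$pools)
})

test_that("an empty file with a valid header loads zero records", {
  d <- synthetic_design("tiny")
  g <- generate_dataset(d, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  generate_fixture_csv(g$table[0, ], path)
  res <- read_database(path)
  expect_equal(res$report$n_loaded, 0)
  expect_equal(nrow(res$table), 0)
  expect_equal(nrow(count_summary(res$table)), 0)
})

test_that("rows violating invariants are rejected with reasons, not fatally", {
  good <- obs_tibble(c(30, 12), pool = c("protein", "carbohydrate"))
  bad <- dplyr::bind_rows(
    obs_tibble(-4),                                   # negative value
    obs_tibble(30, phylum = "Fungi"),                 # outside the vocabulary
    obs_tibble(130),                                  # %DW above 100
    obs_tibble(25, protein_method = "not_applicable") # protein without method
  )
  tab <- dplyr::bind_rows(good, bad)
  tab$value <- as.character(tab$value)
  tab$value[nrow(tab)] <- "n.d."                      # unparseable numeric
  path <- withr::local_tempfile(fileext = ".csv")
  generate_fixture_csv(tab, path)
  res <- read_database(path)
  expect_equal(res$report$n_loaded, 2)
  expect_equal(res$report$n_rejected, 4)
  expect_setequal(
    res$report$rejections$reason,
    c("negative value", "unknown phylum", "percent dry weight above 100",
      "unparseable numeric value")
  )
  expect_equal(res$report$n_loaded + res$report$n_rejected, res$report$n_input)
  j <- jsonlite::fromJSON(validation_report_json(res$report))
  expect_equal(j$n_rejected, 4)
})

test_that("exact duplicate rows are dropped keeping the first occurrence", {
  tab <- dplyr::bind_rows(obs_tibble(30), obs_tibble(30), obs_tibble(31))
  path <- withr::local_tempfile(fileext = ".csv")
  generate_fixture_csv(tab, path)
  res <- read_database(path)
  expect_equal(res$report$n_loaded, 2)
  expect_equal(res$report$rejections$reason, "duplicate row")
})

test_that("missing mandatory columns are a fatal error naming the column", {
  tab <- obs_tibble(30)
  path <- withr::local_tempfile(fileext = ".csv")
  generate_fixture_csv(tab, path)
  txt <- readr::read_csv(path, show_col_types = FALSE)
  txt$value <- NULL
  readr::write_csv(txt, path)
  expect_error(read_database(path), "value")
})

test_that("regime filters apply the positive condition definitions and are idempotent", {
  tab <- dplyr::bind_rows(
    obs_tibble(30, study_id = "a"),                                  # active
    obs_tibble(31, study_id = "b", culture_system = "turbidostat"),  # active
    obs_tibble(32, study_id = "c", culture_system = "semi_continuous"), # active
    obs_tibble(33, study_id = "d", culture_system = "chemostat"),    # excluded
    obs_tibble(34, study_id = "e", nutrient_status = "limited"),     # excluded
    obs_tibble(35, study_id = "f", growth_phase = "stationary"),     # stationary
    obs_tibble(36, study_id = "g", growth_phase = "unknown"),        # neither
    obs_tibble(37, study_id = "h", nutrient_status = "unknown")      # neither
  )
  active <- filter_condition(tab, "active_growth")
  expect_setequal(active$study_id, c("a", "b", "c"))
  expect_identical(
    tibble::as_tibble(filter_condition(active, "active_growth")),
    tibble::as_tibble(active)
  )
  stat <- filter_condition(tab, "stationary")
  expect_equal(stat$study_id, "f")
  only_lag <- filter_condition(obs_tibble(30, growth_phase = "lag"), "active_growth")
  expect_equal(nrow(only_lag), 0)
})

test_that("comparison and grand analysis sets partition on the sparse phyla", {
  tab <- dplyr::bind_rows(
    obs_tibble(rep(30, 10), phylum = "Bacillariophyta",
               species_key = "Thalassiosira pseudonana"),
    obs_tibble(rep(28, 5), phylum = "Euglenozoa", species_key = "Euglena gracilis"),
    obs_tibble(26, phylum = "Rhodophyta", species_key = "Porphyridium cruentum")
  )
  sets <- phylum_analysis_sets(tab)
  expect_equal(nrow(sets$comparison), 10)
  expect_equal(nrow(sets$grand), 16)
  dropped <- dplyr::anti_join(sets$grand, sets$comparison,
                              by = names(tibble::as_tibble(sets$grand)))
  expect_setequal(dropped$phylum, c("Euglenozoa", "Rhodophyta"))

  no_sparse <- obs_tibble(c(30, 31), phylum = "Chlorophyta")
  sets2 <- phylum_analysis_sets(no_sparse)
  expect_identical(tibble::as_tibble(sets2$comparison), tibble::as_tibble(sets2$grand))
})
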