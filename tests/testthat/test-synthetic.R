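test_that("the generator is deterministic and collapses to the location without noise", {
  d <- synthetic_design("tiny", pools = "protein", frac_n_derived = 0)
  g0 <- generate_dataset(d, synthetic_truth(32.2, 0, 0, 0), seed = 1)
  expect_true(all(g0$table$value == 32.2))
  g1 <- generate_dataset(synthetic_design("table3_protein"), seed = 17)
  g2 <- generate_dataset(synthetic_design("table3_protein"), seed = 17)
  expect_identical(g1$table, g2$table)
  expect_identical(g1$truth$phylum_effects, g2$truth$phylum_effects)
  g3 <- generate_dataset(synthetic_design("table3_protein"), seed = 18)
  expect_false(identical(g1$table$value, g3$table$value))
})

test_that("preset designs carry the intended unbalanced layouts", {
  t3 <- synthetic_design("table3_protein")
  per_phylum <- tapply(t3$species_table$n_obs, t3$species_table$phylum, sum)
  expect_equal(
    as.integer(per_phylum[c("Cyanobacteria", "Chlorophyta", "Cryptophyta",
                            "Bacillariophyta", "Haptophyta", "Ochrophyta",
                            "Dinophyta")]),
    c(25L, 75L, 16L, 82L, 76L, 19L, 22L)
  )
  expect_true(all(t3$species_table$n_obs >= 1))
  # Zipf allocation concentrates observations on the first species
  expect_gt(max(t3$species_table$n_obs), 10 * min(t3$species_table$n_obs))
  tiny <- synthetic_design("tiny")
  expect_equal(nrow(generate_dataset(tiny, seed = 1)$table), 60 * 3)
})

test_that("harmonization inverts the generator's N-derived inflation bit-exactly", {
  g <- generate_dataset(synthetic_design("table3_protein"), seed = 23)
  flagged <- g$table$protein_method == "n_derived"
  expect_gt(mean(flagged), 0.25)  # close to the designed 0.37
  corrected <- correct_protein(g$table)
  truth_vals <- g$truth$model_values$model_value[
    match(corrected$obs_id, g$truth$model_values$obs_id)]
  expect_identical(corrected$value, truth_vals)
  # uncorrected flagged eukaryote rows really are inflated on disk
  eu <- flagged & g$table$phylum != "Cyanobacteria"
  expect_true(all(g$table$value[eu] > truth_vals[eu]))
})

test_that("generated effects reproduce their generating moments at large n", {
  big <- synthetic_design(
    species_table = tibble::tibble(
      phylum = "Chlorophyta",
      species_key = paste0("sp", 1:10000),
      n_obs = 1L
    ),
    pools = "protein", frac_n_derived = 0
  )
  tr <- synthetic_truth(32.2, 5.6, 6.2, 7.2)
  g <- generate_dataset(big, tr, seed = 33)
  eff <- g$truth$species_effects$effect
  expect_equal(sd(eff), 6.2, tolerance = 3 / sqrt(2 * length(eff)) * 6.2 / 6.2 + 0.15)
  expect_equal(mean(eff), 0, tolerance = 3 * 6.2 / sqrt(length(eff)))
})

test_that("zero truncation is reported and warned above 10%", {
  d <- synthetic_design("tiny", pools = "protein", frac_n_derived = 0)
  expect_warning(
    g <- generate_dataset(d, synthetic_truth(1, 0, 0, 10), seed = 3),
    "truncation"
  )
  expect_gt(g$truth$clip_rate, 0.10)
  expect_true(all(g$table$value >= 0))
})

test_that("mixed-regime fixtures split exactly as designed after a round-trip", {
  d <- synthetic_design("tiny", pools = "protein")
  act <- generate_dataset(d, seed = 4)$table
  stat <- generate_dataset(d, seed = 5)$table
  stat$growth_phase <- "stationary"
  stat$study_id <- paste0("stat_", stat$study_id)
  path <- withr::local_tempfile(fileext = ".csv")
  generate_fixture_csv(dplyr::bind_rows(act, stat), path)
  res <- read_database(path)
  expect_equal(res$report$n_rejected, 0)
  expect_equal(nrow(filter_condition(res$table, "active_growth")), nrow(act))
  expect_equal(nrow(filter_condition(res$table, "stationary")), nrow(stat))
})

test_that("a zero among-phyla variance yields concentrated sigma and quiet contrasts", {
  d <- synthetic_design("table3_protein")
  cfg <- sampler_config("test", chains = 2, iterations = 1500)
  run_case <- function(sigma_phylum, seed_off) {
    vapply(1:10, function(r) {
      g <- generate_dataset(d, synthetic_truth(32.2, sigma_phylum, 6.2, 7.2),
                            seed = seed_off + r)
      fit <- fit_hierarchical(correct_protein(g$table), config = cfg,
                              seed = seed_off + 50 + r, keep_species = FALSE)
      c(sig_p = median(sigma_draws(fit)[, "sigma_phylum"]),
        signif = mean(pairwise_contrasts(fit)$significant))
    }, numeric(2))
  }
  null_case <- run_case(0, 400)
  alt_case <- run_case(5.6, 700)
  # under a zero among-phyla variance the sigma_P posterior concentrates far
  # below its level under the generating alternative
  expect_lt(median(null_case["sig_p", ]), median(alt_case["sig_p", ]) / 2)
  # and phylum contrasts stay non-significant in at least 90% of pair-tests
  expect_lt(mean(null_case["signif", ]), 0.10)
})

test_that("more observations per species reduce the error on species means", {
  tr <- synthetic_truth(32.2, 5.6, 6.2, 7.2)
  cfg <- sampler_config("test", chains = 2, iterations = 1500)
  rmse_for <- function(n_obs, seed_off) {
    d <- synthetic_design(species_table = tibble::tibble(
      phylum = rep(c("Chlorophyta", "Haptophyta"), each = 6),
      species_key = paste0("sp", 1:12), n_obs = n_obs
    ), pools = "protein", frac_n_derived = 0)
    errs <- unlist(lapply(1:6, function(r) {
      g <- generate_dataset(d, tr, seed = seed_off + r)
      fit <- fit_hierarchical(g$table, config = cfg, seed = seed_off + 50 + r)
      est <- apply(species_draws(fit), 2, median)
      eff <- g$truth$species_effects
      ph <- g$truth$phylum_effects
      truth <- 32.2 + ph$effect[match(eff$phylum, ph$phylum)] + eff$effect
      est[eff$species_key] - truth
    }))
    sqrt(mean(errs^2))
  }
  expect_lt(rmse_for(20L, 600), rmse_for(2L, 600))
})
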