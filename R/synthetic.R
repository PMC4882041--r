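# split `total` observations over `k` species with Zipf-like (1/rank)
# weights: a few heavily studied species dominate, the rest are sparse,
# mimicking the unbalanced sampling of literature compilations
.allocate_obs <- function(total, k) {
  stopifnot(total >= k, k >= 1)
  w <- 1 / seq_len(k)
  extra <- total - k
  alloc <- rep(1L, k)
  if (extra > 0) {
    raw <- extra * w / sum(w)
    add <- floor(raw)
    rem <- extra - sum(add)
    if (rem > 0) {
      frac_order <- order(raw - add, decreasing = TRUE)
      add[frac_order[seq_len(rem)]] <- add[frac_order[seq_len(rem)]] + 1L
    }
    alloc <- alloc + as.integer(add)
  }
  alloc
}

#' Synthetic study designs
#'
#' Builds the sampling layout (phyla, species per phylum, observations per
#' species) used by [generate_dataset()]. Three presets are shipped:
#' `"tiny"` (3 phyla x 4 species x 5 observations, three pools — fast smoke
#' runs), `"table3_protein"` (7 phyla with the heavily unbalanced per-phylum
#' protein observation counts 25/75/16/82/76/19/22 of the curated active-growth
#' database, Zipf-allocated over species), and `"stress_unbalanced"` (a
#' single species dominating its phylum). A custom design can be given via
#' `species_table`.
#'
#' @param preset Preset name, ignored when `species_table` is supplied.
#' @param species_table Optional tibble with `phylum`, `species_key`,
#'   `n_obs`.
#' @param pools Macromolecular pools to generate.
#' @param frac_n_derived Fraction of protein rows flagged as
#'   nitrogen-derived (default 0.37, the observed share of N-based protein
#'   assays in the curated pooled protein set).
#' @param basis Measurement basis for generated rows.
#' @return An object of class `macro_design`.
#' @export
synthetic_design <- function(preset = c("tiny", "table3_protein", "stress_unbalanced"),
                             species_table = NULL, pools = NULL,
                             frac_n_derived = 0.37,
                             basis = "percent_dry_weight") {
  if (is.null(species_table)) {
    preset <- match.arg(preset)
    species_table <- switch(preset,
      tiny = {
        phyla <- c("Cyanobacteria", "Chlorophyta", "Bacillariophyta")
        tibble::tibble(
          phylum = rep(phyla, each = 4),
          species_key = paste0(rep(phyla, each = 4), " sp", rep(1:4, 3)),
          n_obs = 5L
        )
      },
      table3_protein = {
        phyla <- c("Cyanobacteria", "Chlorophyta", "Cryptophyta",
                   "Bacillariophyta", "Haptophyta", "Ochrophyta", "Dinophyta")
        totals <- c(25L, 75L, 16L, 82L, 76L, 19L, 22L)
        n_species <- c(8L, 22L, 4L, 28L, 12L, 6L, 9L)
        dplyr::bind_rows(lapply(seq_along(phyla), function(i) {
          tibble::tibble(
            phylum = phyla[i],
            species_key = paste0(phyla[i], " sp", seq_len(n_species[i])),
            n_obs = .allocate_obs(totals[i], n_species[i])
          )
        }))
      },
      stress_unbalanced = {
        tibble::tibble(
          phylum = c(rep("Haptophyta", 5), rep("Chlorophyta", 5), rep("Dinophyta", 2)),
          species_key = c(paste0("Haptophyta sp", 1:5),
                          paste0("Chlorophyta sp", 1:5),
                          paste0("Dinophyta sp", 1:2)),
          n_obs = c(50L, 1L, 1L, 1L, 1L, rep(3L, 5), 1L, 20L)
        )
      }
    )
    if (is.null(pools)) {
      pools <- if (preset == "tiny") c("protein", "carbohydrate", "lipid") else "protein"
    }
  } else {
    preset <- "custom"
    stopifnot(all(c("phylum", "species_key", "n_obs") %in% names(species_table)))
    if (is.null(pools)) pools <- "protein"
  }
  stopifnot(all(species_table$n_obs >= 1))
  structure(list(preset = preset, species_table = tibble::as_tibble(species_table),
                 pools = pools, frac_n_derived = frac_n_derived, basis = basis),
            class = "macro_design")
}

#' Generating parameters for the synthetic hierarchy
#'
#' Defaults describe percent-dry-weight protein under active growth: overall
#' location 32.2 (the meta-analytic grand median) and SDs 5.6 / 6.2 / 7.2
#' for the among-phyla, among-species-within-phyla and residual levels —
#' the among-phyla value is the SD of the seven phylum-level protein
#' medians, and the other two follow from scaling the reported 42/31/25
#' percent variance split for protein to that component.
#'
#' @param mu Overall location.
#' @param sigma_phylum,sigma_species,sigma_resid Level SDs (>= 0).
#' @return An object of class `macro_truth_params`.
#' @export
synthetic_truth <- function(mu = 32.2, sigma_phylum = 5.6,
                            sigma_species = 6.2, sigma_resid = 7.2) {
  stopifnot(sigma_phylum >= 0, sigma_species >= 0, sigma_resid >= 0)
  structure(list(mu = mu, sigma_phylum = sigma_phylum,
                 sigma_species = sigma_species, sigma_resid = sigma_resid),
            class = "macro_truth_params")
}

#' Default per-pool generating parameters
#'
#' Percent-dry-weight locations from the meta-analytic grand medians
#' (protein 32.2, lipid 17.3, carbohydrate 15.0) with level SDs scaled to
#' each pool's spread.
#'
#' @param pools Pool names.
#' @return Named list of [synthetic_truth()] objects.
#' @export
default_truths <- function(pools) {
  all <- list(
    protein = synthetic_truth(32.2, 5.6, 6.2, 7.2),
    lipid = synthetic_truth(17.3, 3.0, 3.3, 3.9),
    carbohydrate = synthetic_truth(15.0, 3.0, 3.5, 4.0)
  )
  missing <- setdiff(pools, names(all))
  if (length(missing)) stop("no default truth for pool(s): ",
                            paste(missing, collapse = ", "))
  all[pools]
}

#' Generate a synthetic observation table with ground truth
#'
#' Draws phylum effects, species effects and residuals from the three-level
#' normal model, producing an observation table in the canonical schema
#' (active-growth metadata: exponential phase, nutrient-sufficient, batch
#' culture) together with the generating truth. Percent-dry-weight values
#' are truncated at zero, with the truncation rate reported (and a warning
#' above 10%). A seeded fraction of protein rows is flagged `n_derived`;
#' for eukaryotic phyla those stored values are pre-multiplied by 6.25/4.78,
#' so that [correct_protein()] inverts them exactly back to the model-scale
#' values recorded in the truth object (Cyanobacteria are never corrected,
#' so their flagged rows are stored unchanged). Deterministic given `seed`.
#'
#' @param design A [synthetic_design()].
#' @param truth A [synthetic_truth()] (single-pool designs) or a named list
#'   of them, one per pool; `NULL` uses [default_truths()].
#' @param seed Integer seed (mandatory).
#' @return A list with `table` (observation tibble with an `obs_id` column)
#'   and `truth` (class `macro_truth`: parameters, realized effects, and
#'   per-row model values).
#' @export
generate_dataset <- function(design, truth = NULL, seed) {
  stopifnot(inherits(design, "macro_design"), !missing(seed))
  if (is.null(truth)) truth <- default_truths(design$pools)
  if (inherits(truth, "macro_truth_params")) {
    stopifnot(length(design$pools) == 1)
    truth <- setNames(list(truth), design$pools)
  }
  stopifnot(all(design$pools %in% names(truth)))

  st <- design$species_table
  phyla <- sort(unique(st$phylum))
  sp_phylum <- st$phylum
  set.seed(as.integer(seed))

  rows <- list(); effects_ph <- list(); effects_sp <- list()
  clip_n <- 0L; total_n <- 0L
  for (pool in design$pools) {
    tp <- truth[[pool]]
    P_eff <- setNames(rnorm(length(phyla), 0, tp$sigma_phylum), phyla)
    S_eff <- rnorm(nrow(st), 0, tp$sigma_species)
    idx <- rep(seq_len(nrow(st)), st$n_obs)
    obs_j <- sequence(st$n_obs)
    eps <- rnorm(length(idx), 0, tp$sigma_resid)
    y <- tp$mu + P_eff[sp_phylum[idx]] + S_eff[idx] + eps
    clipped <- design$basis == "percent_dry_weight" & y < 0
    y[clipped] <- 0
    clip_n <- clip_n + sum(clipped); total_n <- total_n + length(y)

    n_derived <- rep(FALSE, length(y))
    value <- y
    if (pool == "protein") {
      n_derived <- rbinom(length(y), 1, design$frac_n_derived) == 1
      # Cyanobacteria N-derived values are reported as-is (they are never
      # corrected downstream); eukaryote flagged rows are stored inflated by
      # 6.25/4.78 so that correct_protein() inverts them
      inflate <- n_derived & sp_phylum[idx] != "Cyanobacteria"
      value[inflate] <- y[inflate] * (.n_factor_standard / .n_factor_corrected)
      # rebind the truth-side model value through the same floating-point
      # path the harmonizer takes, so correction inverts bit-exactly
      y[inflate] <- value[inflate] * (.n_factor_corrected / .n_factor_standard)
    }

    rows[[pool]] <- tibble::tibble(
      study_id = sprintf("study_%03d", obs_j),
      phylum = sp_phylum[idx],
      species_key = st$species_key[idx],
      habitat = "marine",
      culture_system = "batch",
      growth_phase = "exponential",
      nutrient_status = "sufficient",
      pool = pool,
      basis = design$basis,
      value = value,
      protein_method = ifelse(pool != "protein", "not_applicable",
                              ifelse(n_derived, "n_derived", "peptide_or_amino_acid")),
      replicate = NA_character_,
      model_value = y
    )
    effects_ph[[pool]] <- tibble::tibble(pool = pool, phylum = phyla,
                                         effect = as.numeric(P_eff),
                                         mean = tp$mu + as.numeric(P_eff))
    effects_sp[[pool]] <- tibble::tibble(pool = pool, species_key = st$species_key,
                                         phylum = sp_phylum, effect = S_eff)
  }
  table <- dplyr::bind_rows(rows)
  table$obs_id <- seq_len(nrow(table))
  model_values <- table$model_value
  table$model_value <- NULL
  clip_rate <- clip_n / total_n
  if (clip_rate > 0.10) {
    warning(sprintf("truncation at zero affected %.1f%% of generated values", 100 * clip_rate))
  }
  truth_out <- structure(list(
    params = truth, phylum_effects = dplyr::bind_rows(effects_ph),
    species_effects = dplyr::bind_rows(effects_sp),
    model_values = tibble::tibble(obs_id = table$obs_id, model_value = model_values),
    clip_rate = clip_rate, seed = as.integer(seed), design = design
  ), class = "macro_truth")
  list(table = table, truth = truth_out)
}

#' Write an observation table as a dialect-formatted fixture CSV
#'
#' Writes the table using the source column names of the given dialect so
#' that it round-trips through [read_database()] with zero rejections.
#'
#' @param table An observation tibble (e.g. from [generate_dataset()]).
#' @param path Output file path.
#' @param dialect Dialect list; `NULL` for the packaged default.
#' @return `path`, invisibly.
#' @export
generate_fixture_csv <- function(table, path, dialect = NULL) {
  if (is.null(dialect)) dialect <- read_dialect()
  cols <- dialect$columns
  out <- list()
  for (field in names(cols)) {
    if (field %in% names(table)) out[[cols[[field]]]] <- table[[field]]
  }
  readr::write_csv(tibble::as_tibble(out), path, na = "")
  invisible(path)
}

#' Parameter-recovery and interval-coverage experiment
#'
#' Repeatedly generates data from [generate_dataset()] (fresh effects each
#' replicate), fits the hierarchical model, and reports bias, RMSE and
#' empirical 95% HDI coverage for the three SDs and the phylum-level means
#' (truth for a phylum mean being `mu` + its realized effect). Seeded and
#' reproducible; replicate r uses generation seed `seed + r` and fit seed
#' `seed + 100000 + r`.
#'
#' @param design A [synthetic_design()] (single-pool).
#' @param truth A [synthetic_truth()].
#' @param n_reps Number of replicates (>= 20).
#' @param config Sampler configuration for each fit.
#' @param seed Base seed.
#' @param mass HDI mass for the coverage check.
#' @return A list with `summary` (per-parameter bias/RMSE/coverage) and
#'   `details` (per-replicate estimates).
#' @export
recovery_experiment <- function(design, truth = synthetic_truth(), n_reps = 100,
                                config = sampler_config("test", chains = 2,
                                                        iterations = 2000),
                                seed = 1, mass = 0.95) {
  stopifnot(n_reps >= 20, length(design$pools) == 1)
  details <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    gen <- generate_dataset(design, truth, seed = seed + r)
    tab <- gen$table
    if (design$pools == "protein") tab <- correct_protein(tab)
    fit <- fit_hierarchical(tab, config = config, seed = seed + 100000 + r,
                            keep_species = FALSE)
    sg <- sigma_draws(fit)
    ph <- phylum_draws(fit)
    truth_sigma <- c(truth$sigma_phylum, truth$sigma_species, truth$sigma_resid)
    rows_sigma <- lapply(1:3, function(k) {
      h <- hdi(sg[, k], mass)
      tibble::tibble(rep = r, parameter = colnames(sg)[k],
                     truth = truth_sigma[k], estimate = median(sg[, k]),
                     hdi_low = h[["lower"]], hdi_high = h[["upper"]])
    })
    eff <- gen$truth$phylum_effects
    rows_ph <- lapply(seq_len(ncol(ph)), function(j) {
      tv <- eff$mean[eff$phylum == colnames(ph)[j]]
      h <- hdi(ph[, j], mass)
      tibble::tibble(rep = r, parameter = paste0("phylum_mean:", colnames(ph)[j]),
                     truth = tv, estimate = median(ph[, j]),
                     hdi_low = h[["lower"]], hdi_high = h[["upper"]])
    })
    details[[r]] <- dplyr::bind_rows(c(rows_sigma, rows_ph))
  }
  details <- dplyr::bind_rows(details)
  details$covered <- details$hdi_low <= details$truth & details$truth <= details$hdi_high
  details$group <- sub(":.*$", "", details$parameter)
  summary <- dplyr::summarise(
    dplyr::group_by(details, .data$group),
    bias = mean(.data$estimate - .data$truth),
    rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
    coverage = mean(.data$covered),
    n = dplyr::n(), .groups = "drop"
  )
  list(summary = summary, details = details)
}
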