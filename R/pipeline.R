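#' Run the full meta-analysis pipeline
#'
#' Orchestrates load, regime filtering, protein harmonization, per-pool
#' hierarchical fits, posterior summaries, pairwise contrasts, variance
#' decomposition, log-scale ratio fits, and the stoichiometric C:N
#' prediction from the fitted phylum medians. Fits use the pan-microalgae
#' set (all phyla); phylum-level tables and contrasts are reported for the
#' comparison phyla only (Euglenozoa and Rhodophyta are too sparse for
#' phylum-to-phylum comparison but still inform the grand estimates).
#'
#' @param input Path to a database CSV, or an already validated observation
#'   tibble.
#' @param regime Growth regime passed to [filter_condition()].
#' @param variables Percent-dry-weight pools to fit.
#' @param ratios Also fit the three within-study mass ratios.
#' @param cn Predict phylum-level molar C:N from the fitted medians
#'   (missing pools dropped).
#' @param config Sampler configuration from [sampler_config()].
#' @param seed Base seed; each fit derives its own offset deterministically.
#' @param out_dir Optional directory: summary tables are written as CSV and
#'   a JSON run manifest is recorded (also on failure, with the failed
#'   stage).
#' @param dialect Dialect for file input.
#' @param constants Elemental constants for the C:N step.
#' @return A list of class `macro_bundle` with summaries, contrasts,
#'   variance decompositions, ratio summaries, C:N table, fits and the
#'   manifest.
#' @export
run_pipeline <- function(input, regime = "active_growth",
                         variables = c("protein", "lipid", "carbohydrate"),
                         ratios = TRUE, cn = TRUE,
                         config = sampler_config("test"), seed = 1,
                         out_dir = NULL, dialect = NULL,
                         constants = elemental_constants()) {
  if (length(variables) == 0) stop("no variables requested")
  manifest <- list(regime = regime, variables = variables, seed = seed,
                   sampler = config[c("preset", "chains", "iterations", "thin")],
                   version = as.character(utils::packageVersion("phycomacro")),
                   stages = list(), status = "running")
  finish <- function() {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                  null = "null", pretty = TRUE),
                 file.path(out_dir, "manifest.json"))
    }
  }
  bundle <- tryCatch({
    stage <- "load"
    if (is.character(input)) {
      loaded <- read_database(input, dialect = dialect)
      table <- loaded$table
      manifest$stages$load <- list(n_loaded = loaded$report$n_loaded,
                                   n_rejected = loaded$report$n_rejected)
    } else {
      table <- input
      manifest$stages$load <- list(n_loaded = nrow(table), n_rejected = 0L)
    }

    stage <- "filter"
    filtered <- filter_condition(table, regime)
    sets <- phylum_analysis_sets(filtered)
    comparison_phyla <- sort(unique(sets$comparison$phylum))
    manifest$stages$filter <- list(n_regime = nrow(filtered),
                                   n_comparison = nrow(sets$comparison))

    stage <- "harmonize"
    grand <- sets$grand
    protein_rows <- grand[grand$pool == "protein", , drop = FALSE]
    other_rows <- grand[grand$pool != "protein", , drop = FALSE]
    harmonized <- if (nrow(protein_rows)) {
      dplyr::bind_rows(stratify_protein_method(protein_rows)$pooled, other_rows)
    } else {
      grand
    }
    manifest$stages$harmonize <- list(
      n_protein = nrow(protein_rows),
      n_corrected = if (nrow(protein_rows)) sum(harmonized$conversion_factor != 1, na.rm = TRUE) else 0L
    )

    stage <- "fit"
    fits <- list(); summaries <- list(); contrasts <- list(); vardecomp <- list()
    for (v in variables) {
      sub <- harmonized[harmonized$pool == v &
                          harmonized$basis == "percent_dry_weight", , drop = FALSE]
      if (nrow(sub) == 0) next
      fit <- fit_hierarchical(sub, config = config,
                              seed = seed + match(v, variables))
      fits[[v]] <- fit
      s <- phylum_summary(fit)
      summaries[[v]] <- s[s$level == "grand" | s$name %in% comparison_phyla, ]
      pd <- phylum_draws(fit)
      keep <- intersect(colnames(pd), comparison_phyla)
      if (length(keep) >= 2) contrasts[[v]] <- pairwise_contrasts(pd[, keep, drop = FALSE])
      vardecomp[[v]] <- variance_decomposition(fit)
      manifest$stages$fit[[v]] <- list(
        n_obs = fit$n_obs$total,
        max_rhat = suppressWarnings(max(fit$convergence$parameters$rhat, na.rm = TRUE))
      )
    }

    ratio_fits <- list(); ratio_summaries <- list()
    if (ratios) {
      stage <- "ratios"
      ratio_tab <- build_ratios(harmonized)
      manifest$stages$ratios <- as.list(table(ratio_tab$ratio_kind))
      for (k in sort(unique(ratio_tab$ratio_kind))) {
        sub <- ratio_tab[ratio_tab$ratio_kind == k, , drop = FALSE]
        if (length(unique(sub$species_key)) < 2) next
        fit <- fit_hierarchical(sub, response = "log_value", config = config,
                                seed = seed + 100 + match(k, sort(unique(ratio_tab$ratio_kind))))
        ratio_fits[[k]] <- fit
        s <- summarize_ratios(fit)
        ratio_summaries[[k]] <- s[s$level == "grand" | s$name %in% comparison_phyla, ]
      }
    }

    cn_table <- NULL
    if (cn && length(summaries)) {
      stage <- "cn"
      med <- lapply(names(summaries), function(v) {
        s <- summaries[[v]][summaries[[v]]$level == "phylum", c("name", "median")]
        names(s)[2] <- v
        s
      })
      profiles <- Reduce(function(a, b) dplyr::full_join(a, b, by = "name"), med)
      cn_vals <- vapply(seq_len(nrow(profiles)), function(i) {
        prof <- unlist(profiles[i, -1])
        tryCatch(profile_cn(prof, constants = constants, missing = "drop"),
                 error = function(e) NA_real_)
      }, numeric(1))
      cn_table <- tibble::tibble(phylum = profiles$name, cn_predicted = cn_vals)
    }

    manifest$status <- "ok"
    structure(list(
      data = list(regime_table = filtered, harmonized = harmonized),
      fits = fits, summaries = summaries, contrasts = contrasts,
      variance_decomposition = vardecomp,
      ratio_fits = ratio_fits, ratio_summaries = ratio_summaries,
      cn = cn_table, manifest = manifest
    ), class = "macro_bundle")
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    finish()
    stop(e)
  })
  manifest <- bundle$manifest
  if (!is.null(out_dir)) {
    for (v in names(bundle$summaries)) {
      readr::write_csv(bundle$summaries[[v]], file.path(out_dir, paste0("summary_", v, ".csv")))
      if (!is.null(bundle$contrasts[[v]])) {
        readr::write_csv(bundle$contrasts[[v]], file.path(out_dir, paste0("contrasts_", v, ".csv")))
      }
      readr::write_csv(bundle$variance_decomposition[[v]],
                       file.path(out_dir, paste0("variance_", v, ".csv")))
    }
    for (k in names(bundle$ratio_summaries)) {
      readr::write_csv(bundle$ratio_summaries[[k]], file.path(out_dir, paste0("ratio_", k, ".csv")))
    }
    if (!is.null(bundle$cn)) readr::write_csv(bundle$cn, file.path(out_dir, "cn_predicted.csv"))
  }
  finish()
  bundle
}

#' Protein estimates stratified by measurement method
#'
#' Fits the hierarchical model independently to each protein method stratum
#' — peptide/amino-acid assays, N-derived as reported, N-derived after the
#' non-protein-nitrogen correction, and the pooled set — and reports phylum
#' and grand medians with HDIs and counts. Phyla absent from a stratum are
#' simply absent from its rows.
#'
#' @param table An observation tibble of protein rows (one regime, percent
#'   dry weight).
#' @param config Sampler configuration.
#' @param seed Base seed.
#' @return A tibble of summaries with a `stratum` column.
#' @export
method_strata_report <- function(table, config = sampler_config("test"), seed = 1) {
  if (nrow(table) == 0 || all(table$pool != "protein")) stop("no protein data present")
  strata <- stratify_protein_method(table[table$pool == "protein", , drop = FALSE])
  out <- lapply(seq_along(strata), function(i) {
    s <- strata[[i]]
    if (nrow(s) == 0 || length(unique(s$species_key)) < 2) return(NULL)
    fit <- fit_hierarchical(s, config = config, seed = seed + i, keep_species = FALSE)
    res <- phylum_summary(fit, grand = length(fit$levels$phylum) >= 2)
    res$stratum <- names(strata)[i]
    res
  })
  dplyr::bind_rows(out)
}

#' Marine-versus-freshwater contrast for a pool
#'
#' Re-uses the hierarchical machinery with habitat as the upper grouping
#' level (species nested within habitat, within the selected phylum, or
#' across all phyla when `phylum = NULL`). Returns the habitat medians and
#' the marine-minus-freshwater difference with its 95% HDI; the difference
#' is flagged significant when the interval excludes zero.
#'
#' @param table An observation tibble (protein rows should be harmonized
#'   beforehand if desired; this function pools protein methods itself).
#' @param pool Macromolecular pool to contrast.
#' @param phylum Optional phylum restriction.
#' @param basis Measurement basis.
#' @param config Sampler configuration.
#' @param seed Seed.
#' @return A one-row tibble with medians per habitat, the difference and a
#'   `significant` flag.
#' @export
habitat_contrast <- function(table, pool, phylum = NULL,
                             basis = "percent_dry_weight",
                             config = sampler_config("test"), seed = 1) {
  sub <- table[table$pool == pool & table$basis == basis &
                 table$habitat %in% c("marine", "freshwater"), , drop = FALSE]
  if (!is.null(phylum)) sub <- sub[sub$phylum == phylum, , drop = FALSE]
  if (pool == "protein" && nrow(sub)) sub <- stratify_protein_method(sub)$pooled
  for (h in c("marine", "freshwater")) {
    if (!any(sub$habitat == h)) {
      stop("no ", h, " observations for pool '", pool, "'",
           if (!is.null(phylum)) paste0(" in ", phylum))
    }
  }
  # species nested in habitat: identical species names across habitats are
  # distinct groups
  sub$species_in_habitat <- paste(sub$habitat, sub$species_key, sep = "::")
  fit <- fit_hierarchical(sub, species = "species_in_habitat",
                          phylum = "habitat", config = config, seed = seed,
                          keep_species = FALSE)
  hd <- phylum_draws(fit)
  d <- hd[, "marine"] - hd[, "freshwater"]
  h <- hdi(d)
  tibble::tibble(
    phylum = phylum %||% "all", pool = pool,
    n_marine = as.integer(fit$n_obs$by_phylum[["marine"]]),
    n_freshwater = as.integer(fit$n_obs$by_phylum[["freshwater"]]),
    marine_median = median(hd[, "marine"]),
    freshwater_median = median(hd[, "freshwater"]),
    difference = median(d), hdi_low = h[["lower"]], hdi_high = h[["upper"]],
    significant = h[["lower"]] > 0 | h[["upper"]] < 0
  )
}
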