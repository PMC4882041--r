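# atomic masses (g/mol)
.mass_C <- 12.011
.mass_N <- 14.007

#' Per-macromolecule elemental constants
#'
#' Carbon, nitrogen and phosphorus mass fractions for each macromolecular
#' pool, used by the C:N predictor: protein at the canonical 53% C / 16% N,
#' storage (phosphorus-free) lipid as triacylglycerol, phospholipid as
#' dipalmitoylphosphatidylcholine, carbohydrate as glucose-equivalent, RNA
#' and DNA as residue-averaged polymerized nucleotides, and chlorophyll-a
#' from its molecular formula. The packaged table was verified by
#' reproducing published phylum-level C:N predictions within ±0.2 before
#' being frozen (see the methods vignette). Phosphorus fractions are carried
#' for forward compatibility; no C:P or N:P output is produced.
#'
#' @param path Optional alternative constants CSV with the same columns.
#' @return A tibble with `pool`, `carbon_fraction`, `nitrogen_fraction`,
#'   `phosphorus_fraction`, `provenance`.
#' @export
elemental_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "elemental_constants.csv", package = "phycomacro")
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("pool", "carbon_fraction", "nitrogen_fraction") %in% names(out)))
  stopifnot(all(out$carbon_fraction > 0), all(out$carbon_fraction <= 1),
            all(out$nitrogen_fraction >= 0), all(out$nitrogen_fraction <= 1))
  out
}

#' Split total lipid into phosphorus-free and phospholipid subpools
#'
#' Total lipid is divided as 2/3 phosphorus-free (storage/neutral) lipid and
#' 1/3 phospholipid; the subpools sum to the input exactly.
#'
#' @param lipid Nonnegative total lipid (any unit).
#' @return Named vector `c(lipid_p_free, phospholipid)`.
#' @export
split_lipid <- function(lipid) {
  stopifnot(is.numeric(lipid), all(lipid >= 0))
  p_free <- lipid * (2 / 3)
  c(lipid_p_free = p_free, phospholipid = lipid - p_free)
}

#' Predict molar C:N from a macromolecular profile
#'
#' Converts each pool's mass contribution to moles of carbon and nitrogen
#' using the per-macromolecule elemental constants and returns the molar
#' ratio. Total lipid is first split 2/3 phosphorus-free / 1/3 phospholipid
#' (see [split_lipid()]). The ratio is invariant to uniform rescaling of the
#' profile, so the pools need not sum to 100. Ash is inorganic and never
#' enters the computation.
#'
#' @param profile Named numeric vector or one-row data frame with any of
#'   `protein`, `lipid`, `carbohydrate`, `rna`, `dna`, `chl_a` in percent
#'   dry weight (an `ash` entry is ignored). `NA` entries are handled per
#'   `missing`.
#' @param constants Constants tibble from [elemental_constants()].
#' @param missing `"drop"` omits `NA` pools from the sums; `"impute"`
#'   replaces them with the corresponding entries of `impute_profile`.
#' @param impute_profile Profile supplying values for `missing = "impute"`.
#' @return The molar C:N (a single number).
#' @export
profile_cn <- function(profile, constants = elemental_constants(),
                       missing = c("drop", "impute"), impute_profile = NULL) {
  missing <- match.arg(missing)
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1)
    profile <- unlist(profile[, vapply(profile, is.numeric, logical(1))])
  }
  pools <- c("protein", "lipid", "carbohydrate", "rna", "dna", "chl_a")
  pct <- setNames(rep(NA_real_, length(pools)), pools)
  known <- intersect(names(profile), pools)
  pct[known] <- as.numeric(profile[known])
  if (missing == "impute") {
    if (is.null(impute_profile)) stop("missing = 'impute' needs an impute_profile")
    imp <- setNames(rep(NA_real_, length(pools)), pools)
    k2 <- intersect(names(impute_profile), pools)
    imp[k2] <- as.numeric(unlist(impute_profile)[k2])
    pct[is.na(pct)] <- imp[is.na(pct)]
  }
  pct <- pct[!is.na(pct)]
  if (!length(pct)) stop("profile contains no usable pools")
  if (any(pct < 0)) stop("negative pool percentages")

  if ("lipid" %in% names(pct)) {
    sub <- split_lipid(pct[["lipid"]])
    pct <- c(pct[names(pct) != "lipid"], sub)
  }
  idx <- match(names(pct), constants$pool)
  if (anyNA(idx)) stop("no elemental constants for pool(s): ",
                       paste(names(pct)[is.na(idx)], collapse = ", "))
  mol_c <- sum(pct * constants$carbon_fraction[idx]) / .mass_C
  mol_n <- sum(pct * constants$nitrogen_fraction[idx]) / .mass_N
  if (mol_n <= 0) stop("profile has no nitrogenous pool: C:N undefined")
  mol_c / mol_n
}

#' Posterior C:N from joint draws of phylum-level pool means
#'
#' Applies [profile_cn()] draw-wise across the joint posterior of the
#' phylum-level pool means and summarizes the resulting C:N draws by their
#' median and HDI. The missing-pool rule is applied identically to every
#' draw.
#'
#' @param pool_draws Named list of equal-length draw vectors, one per pool
#'   (e.g. `list(protein = ..., lipid = ..., carbohydrate = ...)`).
#' @param constants,missing,impute_profile Passed to [profile_cn()].
#' @param mass HDI mass.
#' @return A list with `draws`, `median`, `hdi_low`, `hdi_high`.
#' @export
posterior_cn <- function(pool_draws, constants = elemental_constants(),
                         missing = c("drop", "impute"), impute_profile = NULL,
                         mass = 0.95) {
  missing <- match.arg(missing)
  stopifnot(is.list(pool_draws), length(pool_draws) >= 1)
  n <- unique(lengths(pool_draws))
  stopifnot(length(n) == 1)
  draw_mat <- do.call(cbind, pool_draws)
  cn <- vapply(seq_len(n), function(t) {
    profile_cn(setNames(draw_mat[t, ], names(pool_draws)),
               constants = constants, missing = missing,
               impute_profile = impute_profile)
  }, numeric(1))
  h <- hdi(cn, mass)
  list(draws = cn, median = median(cn),
       hdi_low = h[["lower"]], hdi_high = h[["upper"]])
}

#' Reference phylum-level median macromolecular composition
#'
#' Meta-analytic phylum-level medians (percent dry weight) for
#' nutrient-sufficient exponentially growing microalgae, with a pan-microalgae
#' `Grand` row. Protein is given twice: `protein_pooled` combines corrected
#' nitrogen-derived with peptide/amino-acid assays, while `protein_peptide`
#' is restricted to peptide and amino-acid assays, the stratum appropriate
#' for elemental (C:N) work since nitrogen-derived protein is circular there.
#' `NA` marks pools without phylum-level estimates.
#'
#' @return A tibble with one row per phylum plus `Grand`.
#' @export
reference_composition <- function() {
  path <- system.file("extdata", "phylum_reference_medians.csv", package = "phycomacro")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Predict phylum-level molar C:N from reference or fitted medians
#'
#' Runs [profile_cn()] on each phylum's median composition. By default
#' protein comes from the peptide/amino-acid stratum and pools without a
#' phylum-level estimate are dropped from the sums; these defaults were
#' fixed by calibrating against independent published phylum C:N values
#' (see the methods vignette). Imputation of missing pools from the grand
#' medians is available as an option.
#'
#' @param profiles A tibble like [reference_composition()].
#' @param constants Constants from [elemental_constants()].
#' @param protein `"peptide"` or `"pooled"` protein column.
#' @param missing `"drop"` or `"impute"` (from the `Grand` row).
#' @return A tibble with `phylum` and `cn_predicted`.
#' @export
predict_phylum_cn <- function(profiles = reference_composition(),
                              constants = elemental_constants(),
                              protein = c("peptide", "pooled"),
                              missing = c("drop", "impute")) {
  protein <- match.arg(protein)
  missing <- match.arg(missing)
  pcol <- paste0("protein_", protein)
  if (!pcol %in% names(profiles)) pcol <- "protein"
  grand <- profiles[profiles$phylum == "Grand", , drop = FALSE]
  impute_profile <- NULL
  if (missing == "impute") {
    if (nrow(grand) != 1) stop("impute mode needs a 'Grand' row in profiles")
    impute_profile <- c(
      protein = grand[[pcol]], lipid = grand$lipid,
      carbohydrate = grand$carbohydrate, rna = grand$rna,
      dna = grand$dna, chl_a = grand$chl_a
    )
  }
  cn <- vapply(seq_len(nrow(profiles)), function(i) {
    prof <- c(
      protein = profiles[[pcol]][i], lipid = profiles$lipid[i],
      carbohydrate = profiles$carbohydrate[i], rna = profiles$rna[i],
      dna = profiles$dna[i], chl_a = profiles$chl_a[i]
    )
    profile_cn(prof, constants = constants, missing = missing,
               impute_profile = impute_profile)
  }, numeric(1))
  tibble::tibble(phylum = profiles$phylum, cn_predicted = cn)
}
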