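# minimal observation-tibble constructor with canonical defaults;
# arguments recycle tibble-style
obs_tibble <- function(value, phylum = "Chlorophyta", pool = "protein",
                       species_key = "Chlorella vulgaris", study_id = "st1",
                       habitat = "marine", culture_system = "batch",
                       growth_phase = "exponential",
                       nutrient_status = "sufficient",
                       basis = "percent_dry_weight",
                       protein_method = NULL, replicate = NA_character_) {
  if (is.null(protein_method)) {
    protein_method <- ifelse(pool == "protein", "peptide_or_amino_acid",
                             "not_applicable")
  }
  tibble::tibble(
    study_id = study_id, phylum = phylum, species_key = species_key,
    habitat = habitat, culture_system = culture_system,
    growth_phase = growth_phase, nutrient_status = nutrient_status,
    pool = pool, basis = basis, value = value,
    protein_method = protein_method, replicate = replicate
  )
}

# independent exhaustive shortest-window HDI: plain double loop, first
# minimum wins (ties toward the lower window)
hdi_bruteforce <- function(x, mass) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(x[1], x[m])
  for (i in seq_len(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m - 1])
  }
  best
}

# draws with exactly the requested sample mean and SD (for hand-computable
# weighted means)
exact_draws <- function(n, mean, sd, seed) {
  set.seed(seed)
  z <- rnorm(n)
  z <- as.numeric(scale(z))
  mean + sd * z
}
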