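#' Controlled vocabularies for the canonical observation schema
#'
#' The observation table uses closed vocabularies for taxonomy and
#' experimental metadata. Phyla outside `macro_phyla()` are rejected at load;
#' metadata fields that cannot be interpreted fall back to `"unknown"`.
#'
#' @return A character vector of allowed values.
#' @export
macro_phyla <- function() {
  c("Cyanobacteria", "Chlorophyta", "Rhodophyta", "Bacillariophyta",
    "Cryptophyta", "Dinophyta", "Euglenozoa", "Haptophyta", "Ochrophyta")
}

#' @rdname macro_phyla
#' @export
macro_pools <- function() {
  c("protein", "lipid", "carbohydrate", "ash", "rna", "dna", "chl_a")
}

#' @rdname macro_phyla
#' @export
macro_bases <- function() c("percent_dry_weight", "mass_per_cell")

#' @rdname macro_phyla
#' @export
macro_habitats <- function() c("marine", "freshwater", "unknown")

#' @rdname macro_phyla
#' @export
macro_culture_systems <- function() {
  c("batch", "turbidostat", "chemostat", "semi_continuous", "unknown")
}

#' @rdname macro_phyla
#' @export
macro_growth_phases <- function() c("lag", "exponential", "stationary", "unknown")

#' @rdname macro_phyla
#' @export
macro_nutrient_statuses <- function() c("sufficient", "limited", "starved", "unknown")

#' @rdname macro_phyla
#' @export
macro_protein_methods <- function() {
  c("peptide_or_amino_acid", "n_derived", "not_applicable")
}

# phyla too sparsely sampled for phylum-to-phylum comparison; still kept in
# the pan-microalgae (grand) pool
.excluded_comparison_phyla <- c("Euglenozoa", "Rhodophyta")

# canonical column order of an observation table
.canonical_columns <- c(
  "study_id", "phylum", "species_key", "habitat", "culture_system",
  "growth_phase", "nutrient_status", "pool", "basis", "value",
  "protein_method", "replicate"
)
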