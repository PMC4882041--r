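# Nitrogen-to-protein conversion factors (g protein per g N). Nitrogen-based
# protein assays traditionally assume protein is 16% N (factor 6.25) and that
# all measured N is protein; eukaryotic microalgae hold substantial
# non-protein (largely inorganic) N, so their N-derived values are rescaled
# to the 4.78 factor of Lourenco et al. (2004). Cyanobacteria store N as
# protein and peptides and are left uncorrected.
.n_factor_standard <- 6.25
.n_factor_corrected <- 4.78

#' Correct nitrogen-derived protein values for non-protein nitrogen
#'
#' Multiplies N-derived protein values by 4.78/6.25 for all eukaryotic phyla;
#' peptide/amino-acid based values and Cyanobacteria are unchanged. The
#' original value and the applied factor are kept as audit columns
#' (`value_original`, `conversion_factor`), which also make the operation
#' idempotent.
#'
#' @param table An observation tibble containing protein rows only.
#' @return The table with corrected `value` plus audit columns.
#' @export
correct_protein <- function(table) {
  if (nrow(table) > 0 && any(table$pool != "protein")) {
    stop("correct_protein() expects protein rows only")
  }
  if (nrow(table) > 0 && any(table$protein_method == "not_applicable")) {
    stop("protein rows with protein_method = 'not_applicable' violate the schema")
  }
  if ("conversion_factor" %in% names(table)) {
    return(table)  # already corrected; audit column prevents double application
  }
  corrected <- table$protein_method == "n_derived" & table$phylum != "Cyanobacteria"
  factor <- ifelse(corrected, .n_factor_corrected / .n_factor_standard, 1)
  out <- table
  out$value_original <- table$value
  out$conversion_factor <- factor
  out$value <- table$value * factor
  out
}

#' Stratify protein observations by measurement method
#'
#' @param table An observation tibble of protein rows.
#' @return A list of observation tibbles: `peptide` (amino-acid and peptide
#'   assays), `n_uncorrected` (N-derived, as reported), `n_corrected`
#'   (N-derived after [correct_protein()]) and `pooled` (peptide plus
#'   corrected N-derived); `nrow(pooled) == nrow(peptide) + nrow(n_corrected)`.
#' @export
stratify_protein_method <- function(table) {
  if (nrow(table) > 0 && any(table$pool != "protein")) {
    stop("stratify_protein_method() expects protein rows only")
  }
  peptide <- table[table$protein_method == "peptide_or_amino_acid", , drop = FALSE]
  n_raw <- table[table$protein_method == "n_derived", , drop = FALSE]
  n_corrected <- if (nrow(n_raw)) correct_protein(n_raw) else n_raw
  pooled <- dplyr::bind_rows(
    if (nrow(peptide)) correct_protein(peptide) else peptide,
    n_corrected
  )
  list(peptide = peptide, n_uncorrected = n_raw,
       n_corrected = n_corrected, pooled = pooled)
}

#' Build within-study macromolecular mass ratios
#'
#' Forms protein:carbohydrate, protein:lipid and carbohydrate:lipid ratio
#' observations wherever a single measurement cell — the same study, species,
#' culture system, growth phase, nutrient status and basis — contains both
#' pools of a pair. Ratios are never formed across studies, bases or
#' conditions. When replicate indices are present in a cell, pairing is
#' replicate-wise; otherwise each cell contributes one ratio of cell means.
#' Protein values should already be harmonized (see [correct_protein()]).
#' Cells with a zero denominator are skipped (counted in the `n_skipped`
#' attribute), not fatal. Output order is canonical (sorted by cell), so it
#' is invariant to input row order.
#'
#' @param table An observation tibble filtered to one regime.
#' @param policy `"auto"` (replicate-wise when replicate indices exist, else
#'   cell means), `"replicate"`, or `"cell_mean"`.
#' @return A tibble of ratio observations with `ratio_kind`, `ratio_value`
#'   and `log_value` (natural log) columns.
#' @export
build_ratios <- function(table, policy = c("auto", "replicate", "cell_mean")) {
  policy <- match.arg(policy)
  kinds <- list(
    protein_cho   = c("protein", "carbohydrate"),
    protein_lipid = c("protein", "lipid"),
    cho_lipid     = c("carbohydrate", "lipid")
  )
  tab <- tibble::as_tibble(table)
  tab <- tab[tab$pool %in% c("protein", "carbohydrate", "lipid"), , drop = FALSE]
  if (!"replicate" %in% names(tab)) tab$replicate <- NA_character_
  cell_cols <- c("study_id", "species_key", "phylum", "habitat",
                 "culture_system", "growth_phase", "nutrient_status", "basis")

  use_replicate <- switch(policy,
    replicate = TRUE,
    cell_mean = FALSE,
    auto = any(!is.na(tab$replicate) & tab$replicate != "")
  )
  if (!use_replicate) {
    tab <- dplyr::summarise(
      dplyr::group_by(tab, dplyr::across(dplyr::all_of(c(cell_cols, "pool")))),
      value = mean(.data$value), .groups = "drop"
    )
    tab$replicate <- NA_character_
  } else {
    tab <- dplyr::summarise(
      dplyr::group_by(tab, dplyr::across(dplyr::all_of(c(cell_cols, "replicate", "pool")))),
      value = mean(.data$value), .groups = "drop"
    )
  }

  wide <- tidyr::pivot_wider(tab, names_from = "pool", values_from = "value")
  for (p in c("protein", "carbohydrate", "lipid")) {
    if (!p %in% names(wide)) wide[[p]] <- NA_real_
  }
  n_skipped <- 0L
  out <- lapply(names(kinds), function(kind) {
    num <- wide[[kinds[[kind]][1]]]
    den <- wide[[kinds[[kind]][2]]]
    ok <- !is.na(num) & !is.na(den)
    zero <- ok & den == 0
    n_skipped <<- n_skipped + sum(zero)
    keep <- ok & !zero
    if (!any(keep)) return(NULL)
    res <- wide[keep, cell_cols]
    res$ratio_kind <- kind
    res$ratio_value <- num[keep] / den[keep]
    res$log_value <- log(res$ratio_value)
    res
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out)) {
    out <- dplyr::arrange(out, .data$ratio_kind, .data$study_id,
                          .data$species_key, .data$basis)
  } else {
    out <- tibble::tibble(
      study_id = character(), species_key = character(), phylum = character(),
      habitat = character(), culture_system = character(),
      growth_phase = character(), nutrient_status = character(),
      basis = character(), ratio_kind = character(),
      ratio_value = numeric(), log_value = numeric()
    )
  }
  attr(out, "n_skipped_zero_denominator") <- n_skipped
  out
}
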