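# Column-name mapping and value recodes from the distributed database dialect
# to the canonical schema. Versioned so a differently-headed export only needs
# a new mapping file, not code changes.
name: s1-v1
delimiter: ","
columns:
  # canonical_field: column name in the source file
  study_id: source
  phylum: phylum
  species_key: species_key
  genus: genus
  species: species
  strain: strain
  habitat: habitat
  culture_system: culture_system
  growth_phase: growth_phase
  nutrient_status: nutrient_status
  pool: macromolecule
  basis: units
  value: value
  protein_method: protein_method
  replicate: replicate
recodes:
  habitat:
    coastal: marine
    estuarine: marine
    brackish: marine
    fresh water: freshwater
  culture_system:
    semi-continuous: semi_continuous
    semicontinuous: semi_continuous
  growth_phase:
    log: exponential
    exp: exponential
  nutrient_status:
    replete: sufficient
    nutrient-sufficient: sufficient
    deplete: limited
    deficient: limited
  pool:
    chlorophyll a: chl_a
    chlorophyll-a: chl_a
    chla: chl_a
    cho: carbohydrate
  basis:
    "% dry weight": percent_dry_weight
    "percent dry weight": percent_dry_weight
    "pg cell-1": mass_per_cell
    "pg/cell": mass_per_cell
  protein_method:
    amino acid: peptide_or_amino_acid
    peptide: peptide_or_amino_acid
    lowry: peptide_or_amino_acid
    bradford: peptide_or_amino_acid
    bca: peptide_or_amino_acid
    n content: n_derived
    n-derived: n_derived
    kjeldahl: n_derived
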