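pool,carbon_fraction,nitrogen_fraction,phosphorus_fraction,provenance
protein,0.530000,0.160000,0.000000,Geider & LaRoche (2002) canonical protein elemental composition (53% C; 16% N by mass)
lipid_p_free,0.760000,0.000000,0.000000,triacylglycerol-like storage/neutral lipid (e.g. tripalmitin C51H98O6 is 75.9% C)
phospholipid,0.654503,0.019082,0.042195,dipalmitoylphosphatidylcholine C40H80NO8P
carbohydrate,0.400000,0.000000,0.000000,glucose-equivalent C6H12O6 (40.0% C)
rna,0.354977,0.163408,0.096359,residue-averaged polymerized ribonucleotide monophosphates (A/G/C/U)
dna,0.379050,0.170016,0.100255,residue-averaged polymerized deoxyribonucleotide monophosphates (A/T/G/C)
chl_a,0.739337,0.062706,0.000000,chlorophyll-a C55H72MgN4O5
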