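label,source_class,dG_chain_kcal_per_mol,dG_residue_kcal_per_mol,note
FIA,recombinant,-7.85,-0.41,first intermediate amyloid; published per-chain energy
AD_PHF,human_brain,-36.2,-0.50,synthetic placeholder row for an ex vivo fold
AD_SF,human_brain,-43.1,-0.53,synthetic placeholder row for an ex vivo fold
CTE_typeI,human_brain,-31.0,-0.46,synthetic placeholder row for an ex vivo fold
heparin_snake,recombinant,-18.9,-0.38,synthetic placeholder row for a recombinant fold
mouse_seeded_example,mouse_seeded,-30.5,-0.44,synthetic placeholder row
cell_seeded_example,cell_seeded,-28.0,-0.40,synthetic placeholder row
missing_energy_row,recombinant,,,row with blank energies exercises skipping
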