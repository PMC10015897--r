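{
  "version": "1.0",
  "block": "general",
  "descriptors": ["mol_wt", "heavy_atom_count", "n_hydrogens", "n_bonds",
    "n_rings", "n_aromatic_atoms", "frac_aromatic_atoms", "n_aromatic_rings",
    "n_rotatable_bonds", "n_hetero", "n_N", "n_O", "n_S", "n_halogen",
    "frac_sp3_carbons", "max_partial_charge", "min_partial_charge",
    "max_abs_partial_charge", "sum_pos_charge", "logp_additive", "mr_additive",
    "tpsa_like", "labute_asa", "max_estate", "min_estate", "mean_estate",
    "chi0", "chi1", "graph_diameter", "mean_graph_distance", "n_hbd", "n_hba",
    "mean_atomic_mass", "max_degree", "n_double_bonds", "n_triple_bonds"]
}
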