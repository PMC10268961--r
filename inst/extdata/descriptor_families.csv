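descriptor_name,family
pp_MW,physical_properties
pp_logP,physical_properties
pp_TPSA,physical_properties
pp_MR,physical_properties
pp_HBA,physical_properties
pp_HBD,physical_properties
abc_atoms,atom_bond_counts
abc_bonds,atom_bond_counts
abc_carbons,atom_bond_counts
abc_nitrogens,atom_bond_counts
abc_oxygens,atom_bond_counts
abc_sulfurs,atom_bond_counts
abc_halogens,atom_bond_counts
abc_double_bonds,atom_bond_counts
abc_triple_bonds,atom_bond_counts
abc_rings,atom_bond_counts
abc_aromatic_atoms,atom_bond_counts
abc_rotatable,atom_bond_counts
pc_max,partial_charge
pc_min,partial_charge
pc_abs_sum,partial_charge
pc_pos_sum,partial_charge
pc_neg_sum,partial_charge
pc_rel_pos,partial_charge
pc_rel_neg,partial_charge
pc_sd,partial_charge
vsa_q1,subdivided_surface_areas
vsa_q2,subdivided_surface_areas
vsa_q3,subdivided_surface_areas
vsa_q4,subdivided_surface_areas
vsa_q5,subdivided_surface_areas
vsa_q6,subdivided_surface_areas
vsa_q7,subdivided_surface_areas
vsa_polar,subdivided_surface_areas
vsa_hydrophobic,subdivided_surface_areas
khc_chi0,kier_hall_connectivity
khc_chi0v,kier_hall_connectivity
khc_chi1,kier_hall_connectivity
khc_chi1v,kier_hall_connectivity
khc_kappa1,kier_hall_connectivity
khc_kappa2,kier_hall_connectivity
khc_kappa3,kier_hall_connectivity
adm_wiener,adjacency_distance_matrix
adm_balaban_j,adjacency_distance_matrix
adm_diameter,adjacency_distance_matrix
adm_radius,adjacency_distance_matrix
adm_petitjean,adjacency_distance_matrix
adm_eccentric_conn,adjacency_distance_matrix
adm_zagreb_m1,adjacency_distance_matrix
adm_zagreb_m2,adjacency_distance_matrix
phf_donor,pharmacophore_feature
phf_acceptor,pharmacophore_feature
phf_aromatic_rings,pharmacophore_feature
phf_hydrophobe,pharmacophore_feature
phf_cation,pharmacophore_feature
phf_anion,pharmacophore_feature
phf_basic_amine,pharmacophore_feature
phf_carboxylic_acid,pharmacophore_feature
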