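data_mini_synthetic
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1 N N . ALA A 1 1 ? 46.260 -22.642 8.554 1.00 0.00 ? 1 ALA A N 1
ATOM 2 C CA . ALA A 1 1 ? 46.411 -21.191 8.564 1.00 0.00 ? 1 ALA A CA 1
ATOM 3 C C . ALA A 1 1 ? 45.629 -20.548 7.424 1.00 0.00 ? 1 ALA A C 1
ATOM 4 O O . ALA A 1 1 ? 45.013 -19.497 7.596 1.00 0.00 ? 1 ALA A O 1
ATOM 5 C CB . ALA A 1 1 ? 45.956 -20.627 9.901 1.00 0.00 ? 1 ALA A CB 1
ATOM 6 N N . ALA A 1 2 ? 45.659 -21.187 6.258 1.00 0.00 ? 2 ALA A N 1
ATOM 7 C CA . ALA A 1 2 ? 44.954 -20.678 5.088 1.00 0.00 ? 2 ALA A CA 1
ATOM 8 C C . ALA A 1 2 ? 43.455 -20.571 5.350 1.00 0.00 ? 2 ALA A C 1
ATOM 9 O O . ALA A 1 2 ? 42.809 -19.611 4.933 1.00 0.00 ? 2 ALA A O 1
ATOM 10 C CB . ALA A 1 2 ? 45.517 -19.324 4.685 1.00 0.00 ? 2 ALA A CB 1
ATOM 11 N N . ALA A 1 3 ? 42.909 -21.564 6.045 1.00 0.00 ? 3 ALA A N 1
ATOM 12 C CA . ALA A 1 3 ? 41.486 -21.583 6.365 1.00 0.00 ? 3 ALA A CA 1
ATOM 13 C C . ALA A 1 3 ? 40.636 -21.506 5.101 1.00 0.00 ? 3 ALA A C 1
ATOM 14 O O . ALA A 1 3 ? 39.686 -20.727 5.027 1.00 0.00 ? 3 ALA A O 1
ATOM 15 C CB . ALA A 1 3 ? 41.145 -22.837 7.155 1.00 0.00 ? 3 ALA A CB 1
ATOM 16 N N . ALA A 1 4 ? 40.984 -22.319 4.109 1.00 0.00 ? 4 ALA A N 1
ATOM 17 C CA . ALA A 1 4 ? 40.254 -22.344 2.847 1.00 0.00 ? 4 ALA A CA 1
ATOM 18 C C . ALA A 1 4 ? 40.225 -20.964 2.200 1.00 0.00 ? 4 ALA A C 1
ATOM 19 O O . ALA A 1 4 ? 39.175 -20.497 1.758 1.00 0.00 ? 4 ALA A O 1
ATOM 20 C CB . ALA A 1 4 ? 40.880 -23.358 1.901 1.00 0.00 ? 4 ALA A CB 1
ATOM 21 N N . ALA A 1 5 ? 41.383 -20.315 2.147 1.00 0.00 ? 5 ALA A N 1
ATOM 22 C CA . ALA A 1 5 ? 41.492 -18.987 1.554 1.00 0.00 ? 5 ALA A CA 1
ATOM 23 C C . ALA A 1 5 ? 40.547 -18.001 2.233 1.00 0.00 ? 5 ALA A C 1
ATOM 24 O O . ALA A 1 5 ? 39.834 -17.252 1.566 1.00 0.00 ? 5 ALA A O 1
ATOM 25 C CB . ALA A 1 5 ? 42.927 -18.491 1.643 1.00 0.00 ? 5 ALA A CB 1
ATOM 26 N N . ALA A 1 6 ? 40.548 -18.007 3.562 1.00 0.00 ? 6 ALA A N 1
ATOM 27 C CA . ALA A 1 6 ? 39.692 -17.114 4.333 1.00 0.00 ? 6 ALA A CA 1
ATOM 28 C C . ALA A 1 6 ? 38.224 -17.303 3.964 1.00 0.00 ? 6 ALA A C 1
ATOM 29 O O . ALA A 1 6 ? 37.501 -16.332 3.739 1.00 0.00 ? 6 ALA A O 1
ATOM 30 C CB . ALA A 1 6 ? 39.897 -17.349 5.821 1.00 0.00 ? 6 ALA A CB 1
ATOM 31 N N . ALA A 1 7 ? 37.791 -18.558 3.904 1.00 0.00 ? 7 ALA A N 1
ATOM 32 C CA . ALA A 1 7 ? 36.410 -18.876 3.563 1.00 0.00 ? 7 ALA A CA 1
ATOM 33 C C . ALA A 1 7 ? 36.027 -18.288 2.208 1.00 0.00 ? 7 ALA A C 1
ATOM 34 O O . ALA A 1 7 ? 34.971 -17.673 2.064 1.00 0.00 ? 7 ALA A O 1
ATOM 35 C CB . ALA A 1 7 ? 36.205 -20.383 3.562 1.00 0.00 ? 7 ALA A CB 1
ATOM 36 N N . ALA A 1 8 ? 36.893 -18.482 1.219 1.00 0.00 ? 8 ALA A N 1
ATOM 37 C CA . ALA A 1 8 ? 36.647 -17.972 -0.125 1.00 0.00 ? 8 ALA A CA 1
ATOM 38 C C . ALA A 1 8 ? 36.435 -16.462 -0.111 1.00 0.00 ? 8 ALA A C 1
ATOM 39 O O . ALA A 1 8 ? 35.496 -15.952 -0.723 1.00 0.00 ? 8 ALA A O 1
ATOM 40 C CB . ALA A 1 8 ? 37.806 -18.335 -1.041 1.00 0.00 ? 8 ALA A CB 1
#
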