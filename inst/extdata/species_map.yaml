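# Bundled species map: role atoms and united-atom masses (amu) for the
# molecule types understood out of the box.
#
#  CHOL - cholesterol. Frame atoms C13/C18/C10 define the molecular frame
#         (origin C13, x along C13->C18, xz-plane through C13->C10);
#         C6/C11 define the in-plane orientation vector. ring_atoms lists
#         the 17 sites whose density is mapped for sterol-sterol analyses:
#         the ring carbons C1..C15 plus the two off-plane methyls C18/C19.
#  DCHL - the "flat" analogue with the off-plane methyls removed
#         (15 ring sites). Its C18 (and C19) are virtual sites rebuilt by
#         tetrahedral reconstruction from the listed ring neighbors.
#  DSPC / DOPC - di-C18 phosphatidylcholines, united-atom acyl chains
#         C1A..C18A (sn-1) and C1B..C18B (sn-2); leaflet anchor is P.
species:
  CHOL:
    kind: sterol
    frame_atoms: {c13: C13, c18: C18, c10: C10}
    orientation_atoms: {c6: C6, c11: C11}
    ring_atoms: [C1, C2, C3, C4, C5, C6, C7, C8, C9, C10,
                 C11, C12, C13, C14, C15, C18, C19]
    headgroup_anchor: O3
    atom_masses:
      C1: 14.027
      C2: 14.027
      C3: 13.019
      C4: 14.027
      C5: 12.011
      C6: 13.019
      C7: 14.027
      C8: 13.019
      C9: 13.019
      C10: 12.011
      C11: 14.027
      C12: 14.027
      C13: 12.011
      C14: 13.019
      C15: 14.027
      C16: 14.027
      C17: 13.019
      C18: 15.035
      C19: 15.035
      O3: 17.007
      C20: 13.019
      C22: 14.027
      C25: 15.035
  DCHL:
    kind: sterol
    frame_atoms: {c13: C13, c18: C18, c10: C10}
    orientation_atoms: {c6: C6, c11: C11}
    ring_atoms: [C1, C2, C3, C4, C5, C6, C7, C8, C9, C10,
                 C11, C12, C13, C14, C15]
    reconstruct:
      C18: {center: C13, neighbors: [C12, C14, C17], bond_length: 0.153}
      C19: {center: C10, neighbors: [C1, C5, C9], bond_length: 0.153}
    headgroup_anchor: O3
    atom_masses:
      C1: 14.027
      C2: 14.027
      C3: 13.019
      C4: 14.027
      C5: 12.011
      C6: 13.019
      C7: 14.027
      C8: 13.019
      C9: 13.019
      C10: 12.011
      C11: 14.027
      C12: 14.027
      C13: 12.011
      C14: 13.019
      C15: 14.027
      C16: 14.027
      C17: 13.019
      O3: 17.007
      C20: 13.019
      C22: 14.027
      C25: 15.035
  DSPC:
    kind: phospholipid
    sn1_chain_atoms: [C1A, C2A, C3A, C4A, C5A, C6A, C7A, C8A, C9A, C10A,
                      C11A, C12A, C13A, C14A, C15A, C16A, C17A, C18A]
    sn2_chain_atoms: [C1B, C2B, C3B, C4B, C5B, C6B, C7B, C8B, C9B, C10B,
                      C11B, C12B, C13B, C14B, C15B, C16B, C17B, C18B]
    headgroup_anchor: P
    atom_masses:
      C1A: 14.027
      C2A: 14.027
      C3A: 14.027
      C4A: 14.027
      C5A: 14.027
      C6A: 14.027
      C7A: 14.027
      C8A: 14.027
      C9A: 14.027
      C10A: 14.027
      C11A: 14.027
      C12A: 14.027
      C13A: 14.027
      C14A: 14.027
      C15A: 14.027
      C16A: 14.027
      C17A: 14.027
      C18A: 15.035
      C1B: 14.027
      C2B: 14.027
      C3B: 14.027
      C4B: 14.027
      C5B: 14.027
      C6B: 14.027
      C7B: 14.027
      C8B: 14.027
      C9B: 14.027
      C10B: 14.027
      C11B: 14.027
      C12B: 14.027
      C13B: 14.027
      C14B: 14.027
      C15B: 14.027
      C16B: 14.027
      C17B: 14.027
      C18B: 15.035
      P: 30.974
      N: 14.007
  DOPC:
    kind: phospholipid
    sn1_chain_atoms: [C1A, C2A, C3A, C4A, C5A, C6A, C7A, C8A, C9A, C10A,
                      C11A, C12A, C13A, C14A, C15A, C16A, C17A, C18A]
    sn2_chain_atoms: [C1B, C2B, C3B, C4B, C5B, C6B, C7B, C8B, C9B, C10B,
                      C11B, C12B, C13B, C14B, C15B, C16B, C17B, C18B]
    headgroup_anchor: P
    atom_masses:
      C1A: 14.027
      C2A: 14.027
      C3A: 14.027
      C4A: 14.027
      C5A: 14.027
      C6A: 14.027
      C7A: 14.027
      C8A: 14.027
      C9A: 13.019
      C10A: 13.019
      C11A: 14.027
      C12A: 14.027
      C13A: 14.027
      C14A: 14.027
      C15A: 14.027
      C16A: 14.027
      C17A: 14.027
      C18A: 15.035
      C1B: 14.027
      C2B: 14.027
      C3B: 14.027
      C4B: 14.027
      C5B: 14.027
      C6B: 14.027
      C7B: 14.027
      C8B: 14.027
      C9B: 13.019
      C10B: 13.019
      C11B: 14.027
      C12B: 14.027
      C13B: 14.027
      C14B: 14.027
      C15B: 14.027
      C16B: 14.027
      C17B: 14.027
      C18B: 15.035
      P: 30.974
      N: 14.007
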