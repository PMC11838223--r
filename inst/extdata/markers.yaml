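round1:
  erythroid: [HBB, HBA1]
  megakaryocyte: [PF4, PPBP]
  DC: [IL3RA]
  CD14_monocyte: [CD14, S100A9, CSF3R]
  monocyte_progenitor: [MPO, ELANE]
  NK: [GNLY, NKG7]
  T cell: [CD3E, CD3D, CD3G]
  B cell: [CD19, CD79A]
round2:
  T_CD4_naive: [CD4, IL7R, CCR7]
  T_CD8: [CD8A, CD8B, GZMH, GZMK]
  B: [MS4A1, TCL1A, JCHAIN]
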