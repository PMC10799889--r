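# Editable marker panels. `reference` names the subtype labels (or a regex
# when reference_mode: pattern) whose score distribution serves as the
# statistical background for the cutoff.
exhausted:
  genes: [CTLA4, HAVCR2, LAG3, PDCD1, TIGIT]
  reference: ["CD4 SOCS3+", "CD4 naive"]
  reference_mode: exact
cytotoxic:
  genes: [PRF1, IFNG, GNLY, NKG7, GZMK, GZMB, GZMA, CST7, TNFSF10]
  reference: "^CD4"
  reference_mode: pattern
# Myeloid functional panels: bundled editable defaults drawn from commonly
# used macrophage-polarization and function marker sets; replace with your
# own curated lists as needed.
M1:
  genes: [IL1B, TNF, CXCL9, CXCL10, CD80, CD86, IL6, NOS2]
M2:
  genes: [MRC1, CD163, MSR1, CCL22, IL10, CD5L, MARCO, TGFB1]
angiogenesis:
  genes: [VEGFA, HIF1A, PGF, ANGPT2, TEK, FLT1]
phagocytosis:
  genes: [MRC1, CD36, MARCO, MERTK, C1QB, AXL]
anti_inflammatory:
  genes: [IL10, TGFB1, IL4, IL13, MAF]
pro_inflammatory:
  genes: [IL6, IL1B, TNF, CCL2, CCL3, CXCL8]
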