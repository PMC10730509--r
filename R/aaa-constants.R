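# canonical class-A GPCR segment order, N- to C-terminal; H8 is optional
SEGMENT_ORDER <- c(
  "NTERM", "TM1", "ICL1", "TM2", "ECL1", "TM3", "ICL2", "TM4",
  "ECL2", "TM5", "ICL3", "TM6", "ECL3", "TM7", "H8", "CTERM"
)

ICL_SEGMENTS <- c("ICL1", "ICL2", "ICL3")

# 20 canonical residues plus X (unknown)
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)
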