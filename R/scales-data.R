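# Bundled per-residue property scales.
#
# Values are transcribed from their published sources and, where the scale is
# an AAIndex entry, verified against seqinr::aaindex by unit test. Vectors are
# stored in AAIndex residue order (ARNDCQEGHILKMFPSTWYV) and re-keyed here.

.aaindex_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.bundled_scale_values <- list(
  # Consensus normalized hydrophobicity (Eisenberg, 1984); AAIndex EISD840101.
  HNC = c(0.25, -1.76, -0.64, -0.72, 0.04, -0.69, -0.62, 0.16, -0.40, 0.73,
          0.53, -1.10, 0.26, 0.61, -0.07, -0.26, -0.18, 0.37, 0.02, 0.54),
  # A parameter of charge transfer capability (Charton-Charton, 1983).
  CHAM830107 = c(0, 0, 1, 1, 0, 0, 1, 1, 0, 0,
                 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
  # Transfer free energy to surface (Bull-Breese, 1974).
  BULH740101 = c(-0.20, -0.12, 0.08, -0.20, -0.45, 0.16, -0.30, 0.00, -0.12,
                 -2.26, -2.46, -0.35, -1.47, -2.33, -0.98, -0.39, -0.52,
                 -2.01, -2.24, -1.56),
  # Normalized frequency of beta-sheet (Chou-Fasman, 1978); AAIndex CHOP780202.
  CF_BETA = c(0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37, 0.75, 0.87, 1.60,
              1.30, 0.74, 1.05, 1.38, 0.55, 0.75, 1.19, 1.37, 1.47, 1.70),
  # TOP-IDP intrinsic disorder propensity (Campen et al., 2008).
  TOP_IDP = c(0.06, 0.180, 0.007, 0.192, 0.02, 0.318, 0.736, 0.166, 0.303,
              -0.486, -0.326, 0.586, -0.397, -0.697, 0.987, 0.341, 0.059,
              -0.884, -0.510, -0.121)
)

.bundled_scale_descriptions <- c(
  HNC        = "Consensus normalized hydrophobicity scale (Eisenberg, 1984) [AAIndex EISD840101]",
  CHAM830107 = "A parameter of charge transfer capability (Charton-Charton, 1983)",
  BULH740101 = "Transfer free energy to surface (Bull-Breese, 1974)",
  CF_BETA    = "Normalized frequency of beta-sheet (Chou-Fasman, 1978) [AAIndex CHOP780202]",
  TOP_IDP    = "TOP-IDP intrinsic disorder propensity (Campen et al., 2008)"
)

# Residue category sets. The gatekeeper, non-polar and charge-transfer-acceptor
# sets are fixed by the method; aromatic/charged follow the common convention
# with His excluded (overridable via category= arguments taking a residue set).
.residue_categories <- list(
  gatekeeper = c("D", "E", "R", "K", "P"),
  nonpolar = c("A", "G", "I", "L", "M", "P", "V"),
  polar = c("C", "H", "N", "Q", "S", "T", "W", "Y"),
  charged = c("D", "E", "K", "R"),
  aromatic = c("F", "W", "Y"),
  charge_transfer_acceptor = c("D", "E", "N", "Q")
)
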