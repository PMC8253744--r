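H CHAM830107
D A parameter of charge transfer capability (Charton-Charton, 1983)
R PMID:6673484
A Charton, M. and Charton, B.I.
T The dependence of the Chou-Fasman parameters on amino acid side chain
  structure
J J. Theor. Biol. 111, 447-450 (1983)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      0.      0.      1.      1.      0.      0.      1.      1.      0.      0.
      0.      0.      0.      0.      0.      0.      0.      0.      0.      0.
//
H BULH740101
D Transfer free energy to surface (Bull-Breese, 1974)
R PMID:4839053
A Bull, H.B. and Breese, K.
T Surface tension of amino acid solutions: A hydrophobicity scale of the
  amino acid residues
J Arch. Biochem. Biophys. 161, 665-670 (1974)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   -0.20   -0.12    0.08   -0.20   -0.45    0.16   -0.30    0.00   -0.12   -2.26
   -2.46   -0.35   -1.47   -2.33   -0.98   -0.39   -0.52   -2.01   -2.24   -1.56
//
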