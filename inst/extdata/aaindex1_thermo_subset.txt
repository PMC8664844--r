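H FUKS010101
D Surface composition of amino acids in intracellular proteins of
  thermophiles (percent) (Fukuchi-Nishikawa, 2001)
A Fukuchi, S. and Nishikawa, K.
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    4.47    8.48    3.89    7.05    0.29    2.87   16.56    8.29    1.74    3.30
    5.06   12.98    1.71    2.32    5.41    4.27    3.83    0.67    2.75    4.05
//
H FUKS010102
D Surface composition of amino acids in intracellular proteins of
  mesophiles (percent) (Fukuchi-Nishikawa, 2001)
A Fukuchi, S. and Nishikawa, K.
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    6.77    6.87    5.50    8.57    0.31    5.24   12.93    7.95    2.80    2.72
    4.43   10.20    1.87    1.92    4.79    5.41    5.36    0.54    2.26    3.57
//
H ZIMJ680101
D Hydrophobicity (Zimmerman et al., 1968)
A Zimmerman, J.M., Eliezer, N. and Simha, R.
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.83    0.83    0.09    0.64    1.48    0.00    0.65    0.10    1.10    3.07
    2.52    1.60    1.40    2.75    2.70    0.14    0.54    0.31    2.97    1.79
//
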