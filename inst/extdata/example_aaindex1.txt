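H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
R LIT:0807101
A Kyte, J. and Doolittle, R.F.
T A simple method for displaying the hydropathic character of a protein
J J. Mol. Biol. 157, 105-132 (1982)
C JANJ780102    0.922  JANJ790102    0.914
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
      3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H GRAR740102
D Polarity (Grantham, 1974)
R LIT:2004143b
A Grantham, R.
T Amino acid difference formula to help explain protein evolution
J Science 185, 862-864 (1974)
C CHAM820101    0.960  ZIMJ680103    0.912
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      8.1    10.5    11.6    13.0     5.5    10.5    12.3     9.0    10.4     5.2
      4.9    11.3     5.7     5.2     8.0     9.2     8.6     5.4     6.2     5.9
//
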