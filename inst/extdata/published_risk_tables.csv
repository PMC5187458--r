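table,g1,g2,g3,risk,total,rr,ci_low,ci_high
chr1,CC,,,0.81,54,1.08,0.91,1.28
chr1,CT,,,0.68,22,,,
chr1,TT,,,0.5,4,,,
chr1_pooled,CC,,,0.81,54,1.08,0.91,1.28
chr1_pooled,CT/TT,,,0.65,26,0.86,0.64,1.17
chr21,AA,,,0.61,18,0.81,0.55,1.19
chr21,GA,,,0.77,39,,,
chr21,GG,,,0.82,33,,,
chr21_pooled,AA,,,0.61,18,0.81,0.55,1.19
chr21_pooled,GA/GG,,,0.79,72,1.04,0.89,1.23
chr37,AA,,,0.85,27,1.12,0.93,1.36
chr37,GA,,,0.70,23,,,
chr37,GG,,,0.73,44,,,
chr37_pooled,AA,,,0.85,27,1.12,0.93,1.36
chr37_pooled,GA/GG,,,0.72,67,0.95,0.78,1.14
chr1_chr21,CC,GA/GG,,0.81,48,1.07,0.90,1.28
chr1_chr21,CC,AA,,0.83,6,1.10,0.76,1.60
chr1_chr21,CT/TT,GA/GG,,0.74,19,0.97,0.73,1.30
chr1_chr21,CT/TT,AA,,0.33,6,0.44,0.14,1.37
chr1_chr37,CC,GA/GG,,0.79,38,1.04,0.85,1.27
chr1_chr37,CC,AA,,0.88,16,1.15,0.93,1.43
chr1_chr37,CT/TT,GA/GG,,0.61,18,0.81,0.55,1.19
chr1_chr37,CT/TT,AA,,0.75,8,0.99,0.65,1.50
chr21_chr37,AA,GA/GG,,0.62,13,0.81,0.52,1.27
chr21_chr37,AA,AA,,0.60,5,0.79,0.38,1.63
chr21_chr37,GA/GG,GA/GG,,0.75,52,0.99,0.82,1.20
chr21_chr37,GA/GG,AA,,0.89,19,1.18,0.97,1.43
chr1_chr21_chr37,CT/TT,AA,AA,0.50,2,0.66,0.16,2.65
chr1_chr21_chr37,CT/TT,AA,GA/GG,0.25,4,0.33,0.06,1.81
chr1_chr21_chr37,CT/TT,GA/GG,AA,0.80,5,1.06,0.67,1.66
chr1_chr21_chr37,CT/TT,GA/GG,GA/GG,0.73,15,0.97,0.70,1.34
chr1_chr21_chr37,CC,AA,AA,0.50,2,0.66,0.16,2.65
chr1_chr21_chr37,CC,AA,GA/GG,1.00,4,1.32,1.18,1.48
chr1_chr21_chr37,CC,GA/GG,AA,0.93,14,1.23,1.02,1.47
chr1_chr21_chr37,CC,GA/GG,GA/GG,0.76,34,1.01,0.81,1.26
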