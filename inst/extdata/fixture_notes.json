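{
  "table1": [
    "CIAT16514 NT under WD is printed as the run-together token '6.20.37'; stored as mean 6.2 with SEM 0.37 (spacing-loss typo; the alternative parse 6.2/0.37 vs 6.20/0.37 is the same mean at printed precision).",
    "K18 NL under WD SEM is printed '025'; stored as 0.25 (dropped decimal point).",
    "K12 PH under WD SEM is printed 9.20, an order of magnitude above every other PH SEM; stored as printed.",
    "Ecotype labels are normalised: 'CIAT 6384'->'CIAT6384', 'CIAT 6385'->'CIAT6385', 'cv. Basilisk'->'Basilisk', 'cv. Piata'->'Piata', 'cv. Toledo'->'Toledo'."
  ],
  "table2": [
    "K4 RWC under WD SEM is printed '61'; stored as 0.61 (dropped decimal point).",
    "K17 Fv/Fm under WS SEM is printed '004'; stored as 0.04 (dropped decimal point).",
    "CIAT6384 RWC under WD SEM 13.8 and K12 PhiNPQ under WD SEM 0.30 are unusually large but stored as printed."
  ],
  "table4": [
    "Component scores, mean ranking values and numerical ranks stored exactly as printed; the per-component variance contributions used to form the ranking values are not printed, so the ranking values themselves cannot be recomputed from the scores alone - only their descending order (the numerical rank) is checkable."
  ],
  "cluster_sizes": [
    "Sizes 3, 10, 9, 8, 5 (clusters I, IIa, IIb, III, IV) sum to 35.",
    "The source text states cluster III holds 37.1 % of ecotypes while listing 8 members (8/35 = 22.9 %), and cluster II (IIa+IIb = 19) as 54.3 %; shares computed from the stored sizes are 8.6, 28.6, 25.7, 22.9 and 14.3 %. The discrepancy is documented here and not reproduced computationally."
  ]
}
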