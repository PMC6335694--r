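# Spearman rank correlations between each ultra-short HRV feature and
# its 5-min benchmark equivalent (per phase), transcribed from the same
# published 42-subject mental-stress study as reference_trend_codes.csv.
# Every computable coefficient was reported significant (p_rho < 0.05);
# rho is empty where the feature is not computable at that scale.
feature,scale_s,phase,rho,significant
MeanNN,180,rest,0.984,TRUE
MeanNN,120,rest,0.89,TRUE
MeanNN,60,rest,0.975,TRUE
MeanNN,30,rest,0.936,TRUE
MeanNN,180,stress,0.985,TRUE
MeanNN,120,stress,0.937,TRUE
MeanNN,60,stress,0.955,TRUE
MeanNN,30,stress,0.964,TRUE
StdNN,180,rest,0.954,TRUE
StdNN,120,rest,0.875,TRUE
StdNN,60,rest,0.905,TRUE
StdNN,30,rest,0.749,TRUE
StdNN,180,stress,0.962,TRUE
StdNN,120,stress,0.912,TRUE
StdNN,60,stress,0.791,TRUE
StdNN,30,stress,0.64,TRUE
MeanHR,180,rest,0.984,TRUE
MeanHR,120,rest,0.891,TRUE
MeanHR,60,rest,0.975,TRUE
MeanHR,30,rest,0.947,TRUE
MeanHR,180,stress,0.985,TRUE
MeanHR,120,stress,0.938,TRUE
MeanHR,60,stress,0.954,TRUE
MeanHR,30,stress,0.964,TRUE
StdHR,180,rest,0.914,TRUE
StdHR,120,rest,0.789,TRUE
StdHR,60,rest,0.796,TRUE
StdHR,30,rest,0.635,TRUE
StdHR,180,stress,0.971,TRUE
StdHR,120,stress,0.904,TRUE
StdHR,60,stress,0.784,TRUE
StdHR,30,stress,0.696,TRUE
RMSSD,180,rest,0.961,TRUE
RMSSD,120,rest,0.914,TRUE
RMSSD,60,rest,0.946,TRUE
RMSSD,30,rest,0.859,TRUE
RMSSD,180,stress,0.983,TRUE
RMSSD,120,stress,0.928,TRUE
RMSSD,60,stress,0.915,TRUE
RMSSD,30,stress,0.852,TRUE
NN50,180,rest,0.972,TRUE
NN50,120,rest,0.883,TRUE
NN50,60,rest,0.949,TRUE
NN50,30,rest,0.822,TRUE
NN50,180,stress,0.971,TRUE
NN50,120,stress,0.92,TRUE
NN50,60,stress,0.905,TRUE
NN50,30,stress,0.894,TRUE
pNN50,180,rest,0.967,TRUE
pNN50,120,rest,0.882,TRUE
pNN50,60,rest,0.943,TRUE
pNN50,30,rest,0.818,TRUE
pNN50,180,stress,0.969,TRUE
pNN50,120,stress,0.915,TRUE
pNN50,60,stress,0.913,TRUE
pNN50,30,stress,0.881,TRUE
LF,180,rest,0.894,TRUE
LF,120,rest,0.886,TRUE
LF,60,rest,,
LF,30,rest,,
LF,180,stress,0.921,TRUE
LF,120,stress,0.916,TRUE
LF,60,stress,,
LF,30,stress,,
HF,180,rest,0.915,TRUE
HF,120,rest,0.906,TRUE
HF,60,rest,0.901,TRUE
HF,30,rest,,
HF,180,stress,0.925,TRUE
HF,120,stress,0.915,TRUE
HF,60,stress,0.798,TRUE
HF,30,stress,,
LF/HF,180,rest,0.83,TRUE
LF/HF,120,rest,0.839,TRUE
LF/HF,60,rest,,
LF/HF,30,rest,,
LF/HF,180,stress,0.846,TRUE
LF/HF,120,stress,0.807,TRUE
LF/HF,60,stress,,
LF/HF,30,stress,,
TotPow,180,rest,0.897,TRUE
TotPow,120,rest,0.882,TRUE
TotPow,60,rest,,
TotPow,30,rest,,
TotPow,180,stress,0.9,TRUE
TotPow,120,stress,0.905,TRUE
TotPow,60,stress,,
TotPow,30,stress,,
SD1,180,rest,0.961,TRUE
SD1,120,rest,0.914,TRUE
SD1,60,rest,0.945,TRUE
SD1,30,rest,0.862,TRUE
SD1,180,stress,0.983,TRUE
SD1,120,stress,0.928,TRUE
SD1,60,stress,0.915,TRUE
SD1,30,stress,0.852,TRUE
SD2,180,rest,0.956,TRUE
SD2,120,rest,0.865,TRUE
SD2,60,rest,0.876,TRUE
SD2,30,rest,0.707,TRUE
SD2,180,stress,0.941,TRUE
SD2,120,stress,0.898,TRUE
SD2,60,stress,0.755,TRUE
SD2,30,stress,0.694,TRUE
ApEn,180,rest,0.771,TRUE
ApEn,120,rest,0.169,TRUE
ApEn,60,rest,,
ApEn,30,rest,,
ApEn,180,stress,0.918,TRUE
ApEn,120,stress,0.79,TRUE
ApEn,60,stress,,
ApEn,30,stress,,
SampEn,180,rest,0.855,TRUE
SampEn,120,rest,0.666,TRUE
SampEn,60,rest,0.681,TRUE
SampEn,30,rest,,
SampEn,180,stress,0.931,TRUE
SampEn,120,stress,0.826,TRUE
SampEn,60,stress,0.599,TRUE
SampEn,30,stress,,
D2,180,rest,0.922,TRUE
D2,120,rest,0.674,TRUE
D2,60,rest,0.33,TRUE
D2,30,rest,,
D2,180,stress,0.967,TRUE
D2,120,stress,0.876,TRUE
D2,60,stress,0.816,TRUE
D2,30,stress,,
dfa1,180,rest,0.661,TRUE
dfa1,120,rest,0.687,TRUE
dfa1,60,rest,0.637,TRUE
dfa1,30,rest,,
dfa1,180,stress,0.927,TRUE
dfa1,120,stress,0.908,TRUE
dfa1,60,stress,0.799,TRUE
dfa1,30,stress,,
dfa2,180,rest,0.633,TRUE
dfa2,120,rest,0.611,TRUE
dfa2,60,rest,0.673,TRUE
dfa2,30,rest,,
dfa2,180,stress,0.767,TRUE
dfa2,120,stress,0.563,TRUE
dfa2,60,stress,0.485,TRUE
dfa2,30,stress,,
RPlmean,180,rest,0.837,TRUE
RPlmean,120,rest,0.708,TRUE
RPlmean,60,rest,0.645,TRUE
RPlmean,30,rest,,
RPlmean,180,stress,0.901,TRUE
RPlmean,120,stress,0.73,TRUE
RPlmean,60,stress,0.503,TRUE
RPlmean,30,stress,,
RPlmax,180,rest,0.738,TRUE
RPlmax,120,rest,0.588,TRUE
RPlmax,60,rest,0.583,TRUE
RPlmax,30,rest,,
RPlmax,180,stress,0.896,TRUE
RPlmax,120,stress,0.737,TRUE
RPlmax,60,stress,0.678,TRUE
RPlmax,30,stress,,
REC,180,rest,0.88,TRUE
REC,120,rest,0.643,TRUE
REC,60,rest,0.608,TRUE
REC,30,rest,,
REC,180,stress,0.892,TRUE
REC,120,stress,0.689,TRUE
REC,60,stress,0.513,TRUE
REC,30,stress,,
RPadet,180,rest,0.852,TRUE
RPadet,120,rest,0.645,TRUE
RPadet,60,rest,0.495,TRUE
RPadet,30,rest,,
RPadet,180,stress,0.948,TRUE
RPadet,120,stress,0.817,TRUE
RPadet,60,stress,0.642,TRUE
RPadet,30,stress,,
ShanEn,180,rest,0.795,TRUE
ShanEn,120,rest,0.661,TRUE
ShanEn,60,rest,0.614,TRUE
ShanEn,30,rest,,
ShanEn,180,stress,0.907,TRUE
ShanEn,120,stress,0.72,TRUE
ShanEn,60,stress,0.463,TRUE
ShanEn,30,stress,,
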