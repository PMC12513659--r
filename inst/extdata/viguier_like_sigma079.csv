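# SYNTHETIC fixture: generated by vergedist::dataset_fixture(),
# not measured data. Manual distance-matching design emulated on a
# 20-100 cm grid (10 cm steps), responses = per-trial posterior peaks
# at vergence noise sigma = 0.79 deg, summarised per distance by the
# fitted response-density peak (SD across 2000 trials); seed 790.
# columns: distance_cm, estimate_cm, sd_cm
distance_cm,estimate_cm,sd_cm
20,19.2194800639119,1.74250583902495
30,29.213422627515,3.59934028239278
40,36.6531746923717,6.51887412205896
50,45.5934556889447,9.61415599316599
60,49.3865993561909,12.5147495404622
70,57.3492019143907,15.552747271506
80,60.3163840350727,18.7711052538259
90,65.1890060104811,21.2388309472003
100,67.2727030394848,22.8307227757548
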