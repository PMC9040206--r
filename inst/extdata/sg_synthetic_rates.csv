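age_low,age_high,incidence_per_100k_py,mortality_per_100k_py,population
30,35,35.0,35.0,synthetic_overall
35,40,75.0,50.0,synthetic_overall
40,45,135.0,75.0,synthetic_overall
45,50,185.0,115.0,synthetic_overall
50,55,215.0,185.0,synthetic_overall
55,60,230.0,300.0,synthetic_overall
60,65,235.0,500.0,synthetic_overall
65,70,225.0,850.0,synthetic_overall
70,75,210.0,1500.0,synthetic_overall
75,80,200.0,2700.0,synthetic_overall
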