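age_low,age_high,incidence_per_100k_py,mortality_per_100k_py,population
20,25,1.22,4.93,us_white
25,30,7.41,5.31,us_white
30,35,22.97,6.25,us_white
35,40,56.49,8.25,us_white
40,45,116.45,13.07,us_white
45,50,195.25,21.81,us_white
50,55,261.54,36.55,us_white
55,60,302.79,59.79,us_white
60,65,367.57,97.89,us_white
65,70,420.29,159.35,us_white
70,75,434.56,255.81,us_white
75,80,491.54,415.88,us_white
80,85,461.04,677.45,us_white
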