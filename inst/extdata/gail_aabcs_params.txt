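# Gail-model (BCRAT) relative-risk coefficients and attributable risks for
# the Asian-American Breast Cancer Study (AABCS) population, as published
# for the Asian-American extension of the model (Matsuno et al. 2011) and
# distributed with the BCRA R package ("Asian.AABCS").
# Category coding: menarche >=14/12-13/<12 -> 0/1/2;
# first birth <20/20-24/25-29 or nulliparous/>=30 -> 0/1/2/3;
# ever biopsy no/yes -> 0/1; affected first-degree relatives 0/1.
label = Asian.AABCS
coef_menarche = 0.07499257592975
coef_biopsy = 0.55263612260619
coef_first_birth = 0.27638268294593
coef_relatives = 0.79185633720481
coef_biopsy_age50 = 0
coef_firstbirth_relatives = 0
# attributable-risk proportions per age segment (AR; 1-AR rescales
# composite incidence to the baseline-category hazard)
ar_lt50 = 0.52480193573265
ar_ge50 = 0.49683598316097
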