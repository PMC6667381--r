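condition,let_keV_um,total_oh,total_oh_sd,sparse_oh,sparse_oh_sd,sparse_density,sparse_density_sd,sparse_conc_mM,sparse_conc_sd,h2o2,h2o2_sd,o2_consumption,o2_consumption_sd,ratio_h2o2_o2,total_oxidation,total_oxidation_sd
X-ray,NA,0.35,0.01,0.17,0.02,149,15,5.6,1.7,0.26,0.010,0.41,0.042,0.63,2.74,0.217
20 keV/um,20,0.33,0.02,0.15,0.03,142,6,4.7,0.6,0.20,0.015,0.39,0.145,0.51,1.17,0.020
40 keV/um,40,0.31,0.01,0.11,0.02,136,18,4.3,1.7,0.19,0.009,0.28,0.019,0.68,0.94,0.057
60 keV/um,60,0.34,0.01,0.13,0.05,150,37,6.1,4.2,0.19,0.004,0.23,0.031,0.83,0.76,0.098
80 keV/um,80,0.30,0.00,0.12,0.04,155,31,6.6,3.7,0.17,0.005,0.15,0.059,1.13,0.66,0.004
>100 keV/um,NA,0.28,0.01,0.09,0.02,153,28,6.2,3.3,0.17,0.006,0.05,0.125,3.40,0.34,0.064
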