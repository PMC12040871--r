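category,index_kind,year,overall,within,within_percent,between,between_percent
staff,T,2019,0.0559,0.0353,63.16,0.0206,36.84
staff,T,2020,0.0571,0.0370,64.81,0.0201,35.19
staff,T,2021,0.0587,0.0412,70.09,0.0176,29.91
staff,T,2022,0.0575,0.0412,71.74,0.0162,28.26
staff,T,2023,0.0575,0.0423,76.67,0.0152,27.50
staff,L,2019,0.0556,0.0349,62.83,0.0207,37.17
staff,L,2020,0.0560,0.0358,63.95,0.0202,36.05
staff,L,2021,0.0564,0.0389,69.02,0.0175,30.98
staff,L,2022,0.0543,0.0381,70.27,0.0161,29.73
staff,L,2023,0.0552,0.0400,72.51,0.0152,27.49
health_professionals,T,2019,0.0457,0.0207,45.34,0.0250,54.66
health_professionals,T,2020,0.0472,0.0241,50.99,0.0231,49.01
health_professionals,T,2021,0.0476,0.0268,56.24,0.0208,43.76
health_professionals,T,2022,0.0461,0.0272,59.04,0.0189,40.96
health_professionals,T,2023,0.0447,0.0287,64.21,0.0160,35.79
health_professionals,L,2019,0.0438,0.0196,44.70,0.0242,55.30
health_professionals,L,2020,0.0454,0.0254,55.94,0.0225,49.48
health_professionals,L,2021,0.0455,0.0254,55.88,0.0201,44.12
health_professionals,L,2022,0.0434,0.0252,58.08,0.0182,41.92
health_professionals,L,2023,0.0426,0.0270,63.36,0.0156,36.64
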