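year,category_group,category_label,percent
2019,gender,male,44.43
2020,gender,male,43.84
2021,gender,male,43.03
2022,gender,male,41.86
2023,gender,male,41.29
2019,gender,female,55.57
2020,gender,female,56.16
2021,gender,female,56.97
2022,gender,female,58.14
2023,gender,female,58.71
2019,age,<25,2.75
2020,age,<25,3.01
2021,age,<25,3.71
2022,age,<25,4.66
2023,age,<25,4.13
2019,age,25-34,24.03
2020,age,25-34,24.23
2021,age,25-34,25.11
2022,age,25-34,27.28
2023,age,25-34,29.06
2019,age,35-44,30.82
2020,age,35-44,29.66
2021,age,35-44,28.50
2022,age,35-44,27.52
2023,age,35-44,27.00
2019,age,45-54,32.38
2020,age,45-54,31.85
2021,age,45-54,30.85
2022,age,45-54,29.48
2023,age,45-54,28.76
2019,age,>=55,10.02
2020,age,>=55,11.25
2021,age,>=55,11.83
2022,age,>=55,11.05
2023,age,>=55,11.06
2019,tenure,<5,12.02
2020,tenure,<5,12.98
2021,tenure,<5,15.24
2022,tenure,<5,19.28
2023,tenure,<5,21.12
2019,tenure,5-9,12.26
2020,tenure,5-9,12.17
2021,tenure,5-9,12.19
2022,tenure,5-9,12.23
2023,tenure,5-9,12.07
2019,tenure,10-19,20.57
2020,tenure,10-19,21.02
2021,tenure,10-19,21.22
2022,tenure,10-19,21.49
2023,tenure,10-19,22.33
2019,tenure,20-29,29.69
2020,tenure,20-29,28.28
2021,tenure,20-29,26.02
2022,tenure,20-29,23.63
2023,tenure,20-29,22.49
2019,tenure,>=30,21.09
2020,tenure,>=30,23.12
2021,tenure,>=30,24.20
2022,tenure,>=30,24.02
2023,tenure,>=30,23.76
2019,professional_share,health_professionals,71.92
2020,professional_share,health_professionals,72.41
2021,professional_share,health_professionals,72.83
2022,professional_share,health_professionals,73.25
2023,professional_share,health_professionals,76.26
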