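year,staff_total,density_per_10k,health_professional_percent
2019,183820,1.30,71.92
2020,194535,1.38,72.41
2021,205384,1.45,72.83
2022,224205,1.59,73.25
2023,230594,1.64,76.26
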