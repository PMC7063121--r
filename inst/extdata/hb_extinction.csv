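# Molar extinction coefficients of oxy- and deoxyhemoglobin, 1/(mM cm),
# compiled from standard literature tabulations (Prahl compilation).
wavelength_nm,e_o2hb,e_hhb
690,0.2760,2.0520
730,0.3900,1.1022
760,0.5862,1.5485
780,0.7360,1.0851
805,0.8653,0.7504
830,0.9740,0.6930
850,1.0580,0.6913
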