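# Molar extinction coefficients for oxy- and deoxyhaemoglobin,
# W.B. Gratzer / S. Prahl compilation, units 1/(cm * M).
# version: 1
wavelength_nm,e_hbo,e_hbr
760,586.0,1548.52
850,1058.0,691.32
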