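wavelength_nm,HbO2,Hb
532,40.0,40.0
560,33.0,54.0
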