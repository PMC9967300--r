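dye,mu_debye
SQ-H2,12.99
SQ-Cl2,13.41
SQ-Me2,13.73
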