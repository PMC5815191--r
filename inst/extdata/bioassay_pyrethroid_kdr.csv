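genotype,arm,survival
SS,exposed,0.59
SR,exposed,0.72
RR,exposed,0.83
SS,unexposed,0.83
SR,unexposed,0.50
RR,unexposed,0.67
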