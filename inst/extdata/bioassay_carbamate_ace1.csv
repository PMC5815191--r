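genotype,arm,survival
SS,exposed,0.02
SR,exposed,0.56
RR,exposed,0.84
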