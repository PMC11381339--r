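triplet	category
PPW	strong
PPP	strong
DPP	strong
PPN	strong
PPS	medium
PPA	medium
CPP	weak
PPR	weak
PPH	weak
PPL	weak
TPP	weak
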