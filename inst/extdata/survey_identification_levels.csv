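level,n
SPECIES,129671
SPECIES_GROUP,10948
GENUS,4128
GENUS_GROUP,168
ORDER,518
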