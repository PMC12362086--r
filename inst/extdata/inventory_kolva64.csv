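# Illustrative repeat-unit assignment for Kollidon VA64
# (vinylpyrrolidone / vinyl acetate 6:4 copolymer), fractional counts
# weighted by monomer ratio per averaged repeat unit.
group,count
CH2,1.0
CH,1.0
CH2_ring,1.8
C=O,0.6
N_ring,0.6
COO,0.4
CH3,0.4
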