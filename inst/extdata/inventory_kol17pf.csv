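# Illustrative repeat-unit assignment for Kollidon 17PF
# (polyvinylpyrrolidone), per vinylpyrrolidone repeat unit.
group,count
CH2,1
CH,1
CH2_ring,3
C=O,1
N_ring,1
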