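# Illustrative averaged repeat-unit assignment for Eudragit EPO
# (butyl methacrylate / dimethylaminoethyl methacrylate / methyl
# methacrylate 1:2:1), fractional counts per averaged repeat unit.
group,count
CH2,2.25
C,1.0
CH3,2.25
COO,1.0
N_tert,0.5
OCH3,0.25
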