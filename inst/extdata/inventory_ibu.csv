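# Illustrative functional-group assignment for ibuprofen
# (2-(4-isobutylphenyl)propanoic acid).
group,count
CH3,3
CH2,1
CH,2
phenylene,1
COOH,1
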