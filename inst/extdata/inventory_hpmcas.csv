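# Illustrative averaged repeat-unit assignment for HPMCAS (AS-LMP grade):
# anhydroglucose backbone with methoxy, hydroxypropoxy, acetyl and
# succinoyl substitution, fractional counts per substitution degree.
group,count
CH,5
CH2,1.5
O_ether,2.5
OH,0.7
OCH3,1.6
COO,0.8
COOH,0.3
CH3,0.9
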