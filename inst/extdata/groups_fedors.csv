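# Illustrative Fedors group-contribution table (cohesive energy E in J/mol,
# molar volume V in cm^3/mol). Values follow the widely reprinted Fedors
# (1974) compilation; intended as an editable, illustrative database, not a
# canonical chemistry.
group,E,V
CH3,4710,33.5
CH2,4940,16.1
CH,3430,-1.0
C,1470,-19.2
CH2_ring,4940,16.0
CH_arom,4310,13.5
C_arom,4310,-5.5
phenylene,31940,52.4
COOH,27630,28.5
COO,18000,18.0
C=O,17370,10.8
O_ether,3350,3.8
OH,29800,10.0
N_tert,4190,-9.0
N_ring,11720,5.0
OCH3,8050,37.3
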