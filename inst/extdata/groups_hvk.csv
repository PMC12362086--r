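# Illustrative Hoftyzer-van Krevelen group-contribution table.
# Fd, Fp in (J cm^3)^(1/2)/mol; Eh in J/mol; V in cm^3/mol.
# Values follow the van Krevelen compilation; illustrative database.
group,Fd,Fp,Eh,V
CH3,420,0,0,33.5
CH2,270,0,0,16.1
CH,80,0,0,-1.0
C,-70,0,0,-19.2
CH2_ring,270,0,0,16.0
CH_arom,240,0,0,13.5
C_arom,90,0,0,-5.5
phenylene,1270,110,0,52.4
COOH,530,420,10000,28.5
COO,390,490,7000,18.0
C=O,290,770,2000,10.8
O_ether,100,400,3000,3.8
OH,210,500,20000,10.0
N_tert,20,800,5000,-9.0
N_ring,20,800,5000,5.0
OCH3,520,400,3000,37.3
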