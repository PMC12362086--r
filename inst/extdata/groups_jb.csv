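# Illustrative Just-Breitkreutz group-contribution table (solid-state
# oriented re-parameterization of the HVK scheme; values adapted for
# illustration from the pharmaceutical GC literature). Units as HVK.
group,Fd,Fp,Eh,V
CH3,380,0,0,32.0
CH2,255,0,0,15.8
CH,90,0,0,-0.5
C,-60,0,0,-18.0
CH2_ring,255,0,0,15.5
CH_arom,200,0,0,13.0
C_arom,80,0,0,-5.0
phenylene,1060,105,0,51.0
COOH,480,390,8500,28.0
COO,350,450,5800,17.5
C=O,260,700,1700,10.5
O_ether,90,360,2500,3.7
OH,190,470,17000,9.7
N_tert,15,720,4200,-8.5
N_ring,15,720,4200,4.8
OCH3,470,370,2600,36.5
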