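trait,analysis,sigma_G2,sigma_H2,sigma_e2,h2_ref,H2_ref,baker_ref
RDM,N_stress,6.24,3.06,159.74,0.13,0.19,0.80
RDM,joint,15.05,3.07,145.76,0.28,0.33,0.91
RAD,inoculated,11.86,0.35,30.74,0.60,0.61,0.99
SRL,N_stress,84.81,50.23,1019.22,0.22,0.35,0.77
SRSA,inoculated,3587.74,357.63,16801.18,0.44,0.48,0.95
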