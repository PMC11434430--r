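compound,iLOGP,XLOGP2,XLOGP3,WLOGP,MLOGP,SILICOS-IT,milogP,ACD/logP,KOWWIN,ALOGPs
Betulin,4.31,7.82,8.28,7.00,6.00,6.21,7.16,9.01,8.18,5.34
EB355A,4.89,10.15,10.58,9.27,6.61,8.74,8.96,11.62,10.54,6.65
EB365,5.39,10.89,11.15,9.84,6.85,9.27,9.20,12.52,11.55,7.22
EB366,5.70,10.89,11.15,9.84,6.85,9.27,9.08,12.52,11.55,7.25
EB367,5.32,10.15,10.58,9.27,6.61,8.74,8.81,11.62,10.54,6.73
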