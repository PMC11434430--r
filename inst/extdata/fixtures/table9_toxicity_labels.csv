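compound,hepatotoxicity,nephrotoxicity,neurotoxicity,skin_sensitization,cardiotoxicity_hERG_1uM
EB355A,0,0,0,0,1
EB365,0,0,0,0,0
EB366,0,0,0,0,0
EB367,0,0,0,0,0
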