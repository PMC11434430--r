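compound,rm0,b,r,logp_tlc
Betulin,4.81,-0.05,0.989,6.11
EB355A,6.05,-0.07,0.989,7.52
EB365,6.72,-0.07,0.993,8.28
EB366,6.66,-0.07,0.995,8.21
EB367,6.55,-0.07,0.985,8.09
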