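name,rm0,logp_lit,b,r,logp_tlc
Acetanilide,0.57,1.21,-0.01,0.982,1.31
Prednisone,0.72,1.62,-0.01,0.989,1.48
4-Bromoacetophenone,1.82,2.43,-0.02,0.985,2.73
Benzophenone,2.23,3.18,-0.03,0.989,3.19
Anthracene,3.03,4.45,-0.04,0.993,4.10
Dibenzyl,3.51,4.79,-0.04,0.994,4.64
DDT,5.20,6.38,-0.06,0.997,6.56
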