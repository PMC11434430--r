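compound,M,TPSA,nROTB,nHBD,nHBA,MR,logPapp,logKp
Betulin,442.72,40.46,2,2,2,136.30,1.375,-2.789
EB355A,599.89,62.32,6,2,3,182.38,0.630,-2.736
EB365,641.92,68.39,8,1,4,192.12,0.674,-2.732
EB366,641.92,68.39,8,1,4,192.12,0.708,-2.730
EB367,599.89,62.32,6,2,3,182.38,0.660,-2.735
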