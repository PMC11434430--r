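compound,assay,ic50_uM
EB355A,MCF-7,67
EB366,MCF-7,156
EB367,MCF-7,35
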