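name,class,logP,MV
Rha-C10-C10,mono,5.2,490.0
Rha-Rha-C10-C10,di,4.4,630.0
Rha-C10-C12,mono,6.1,560.0
Rha-Rha-C10-C12,di,5.3,700.0
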