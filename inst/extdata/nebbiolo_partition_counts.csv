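category,CVT71,CVT423,CVT185,VARIETAL
HOM_REF,784,403,400,0
HOM_ALT,3606,3113,3245,524899
HET,8496,4398,4425,111424
EXCLUDED,0,0,0,368
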