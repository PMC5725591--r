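category,impact,het,hom_alt
START_LOST,HIGH,9,37
STOP_GAINED,HIGH,54,164
STOP_LOST,HIGH,5,83
SPLICE_SITE_ACCEPTOR,HIGH,15,62
SPLICE_SITE_DONOR,HIGH,15,54
NON_SYNONYMOUS_START,LOW,2,4
SYNONYMOUS_CODING,LOW,3473,11630
SYNONYMOUS_STOP,LOW,6,37
START_GAINED,LOW,136,438
NON_SYNONYMOUS_CODING,MODERATE,3651,13125
DOWNSTREAM,MODIFIER,6809,35311
INTRON,MODIFIER,17142,99189
UPSTREAM,MODIFIER,5196,27463
UTR_3_PRIME,MODIFIER,789,4639
UTR_5_PRIME,MODIFIER,799,2163
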