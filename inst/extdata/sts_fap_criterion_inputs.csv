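group,n_tumors,n_diffuse_positive,n_tn_gt10,n_tn_evaluable,n_overexpressing,percent_overexpressing
Human total,39,32,18,34,33,85
MPNST,10,7,3,9,7,90
UPS,10,9,7,10,9,90
DFSP,9,7,3,7,7,78
MFS,10,9,5,8,9,90
Canine total,53,30,20,44,40,76
PWT,30,22,12,23,25,83
STS NOS,16,5,5,14,10,62
cFS,7,3,3,7,5,71
Feline fFS,24,19,11,22,22,92
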