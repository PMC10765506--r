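strain_id,Santorini,Pelion,Nemea,Goumenissa
S1,FALSE,TRUE,FALSE,FALSE
S2,FALSE,TRUE,FALSE,FALSE
S3,FALSE,TRUE,TRUE,FALSE
S4,FALSE,TRUE,FALSE,TRUE
S5,TRUE,TRUE,FALSE,FALSE
S6,FALSE,TRUE,TRUE,TRUE
S7,FALSE,FALSE,TRUE,TRUE
S8,TRUE,FALSE,TRUE,FALSE
S9,FALSE,TRUE,TRUE,FALSE
S10,TRUE,TRUE,TRUE,TRUE
S11,FALSE,FALSE,TRUE,FALSE
S12,FALSE,FALSE,TRUE,FALSE
S13,FALSE,FALSE,TRUE,FALSE
S14,FALSE,TRUE,TRUE,FALSE
S15,TRUE,FALSE,FALSE,FALSE
S16,TRUE,FALSE,FALSE,TRUE
S17,TRUE,FALSE,FALSE,FALSE
S18,TRUE,FALSE,FALSE,FALSE
S19,FALSE,TRUE,FALSE,TRUE
S20,TRUE,TRUE,TRUE,FALSE
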