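strain_id,red,white
S1,TRUE,FALSE
S2,TRUE,TRUE
S3,TRUE,TRUE
S4,TRUE,TRUE
S5,TRUE,TRUE
S6,TRUE,TRUE
S7,TRUE,TRUE
S8,TRUE,TRUE
S9,TRUE,TRUE
S10,TRUE,TRUE
S11,TRUE,FALSE
S12,TRUE,FALSE
S13,TRUE,FALSE
S14,TRUE,FALSE
S15,FALSE,TRUE
S16,FALSE,TRUE
S17,FALSE,TRUE
S18,FALSE,TRUE
S19,TRUE,FALSE
S20,TRUE,TRUE
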