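strain_id,capacity,sensory_group,preliminary_group,validated
S1,TRUE,B,3-Green,TRUE
S2,FALSE,none,1-Yellow,TRUE
S3,FALSE,none,1-Yellow,TRUE
S4,FALSE,none,1-Yellow,TRUE
S5,TRUE,B,2-Grey,TRUE
S6,TRUE,A,2-Grey,TRUE
S7,FALSE,none,3-Green,TRUE
S8,FALSE,none,2-Grey,TRUE
S9,TRUE,C,1-Yellow,TRUE
S10,TRUE,A,3-Green,TRUE
S11,TRUE,D,4-Pink,TRUE
S12,TRUE,A,2-Grey,TRUE
S13,FALSE,none,3-Green,TRUE
S14,TRUE,B,2-Grey,TRUE
S15,TRUE,D,4-Pink,TRUE
S16,TRUE,A,2-Grey,TRUE
S17,TRUE,C,1-Yellow,TRUE
S18,TRUE,A,3-Green,TRUE
S19,FALSE,none,2-Grey,TRUE
S20,TRUE,B,3-Green,TRUE
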