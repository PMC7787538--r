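# Synthetic specification rule base for the type-2-diabetes pathway
# illustration. Constructed for demonstration and testing of the inference
# engine; NOT a published rule set.
R1: MP_SMB & MP_CTM -> MP_TRXN
R2: MP_TRXN -> MP_ATM
R3: MP_ATM & MP_SMB -> MP_RRR
R4: MP_RRR | MP_GLU -> MP_TRAN
R5: MP_GLU & MP_INS -> MP_LIP
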