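reaction_id,max_uptake
Diet_EX_glc_D[d],10
Diet_EX_asp_L[d],5
Diet_EX_cys_L[d],2
Diet_EX_so3[d],2
Diet_EX_tchola[d],2
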