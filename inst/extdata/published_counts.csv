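well_id,kind,assay,maternal_genotype,n_total,n_ch1_pos,n_ch2_pos,n_double_pos
cc_sample_1,sample,RHCE_rs676785,cc,14000,379,44,0
cc_sample_2,sample,RHCE_rs676785,cc,14000,517,54,0
ntc_1,ntc,RHCE_rs676785,,15646,1,0,0
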