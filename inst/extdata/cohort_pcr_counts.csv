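cohort,n_pcr,n_total
training,167,431
external_validation,590,1595
immunotherapy,55,88
multi_omics,92,165
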