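preset: table2_nonlinear_T1M3_corr03
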