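reason,n,residual_carcinoma,mastectomy_first_reexcision
ink_on_tumor,25,17,11
margin_under_1mm,13,9,4
other,4,0,0
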