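group,n,multifocal,mri_size_mean,mri_size_sd,path_size_mean,path_size_sd
no_reexcision,67,16,2.0,0.8,1.7,0.8
one_reexcision,31,17,2.6,1.7,1.3,0.9
two_or_more_reexcisions,11,1,2.5,1.9,1.5,0.9
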