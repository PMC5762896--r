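group,n,multifocal
no_reexcision,67,16
reexcision,42,17
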