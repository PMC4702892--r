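cancer_type	n_samples	n_breakpoints
GBM	27	55874
BRC	15	22077
LUAD	17	36086
OV	23	56435
HN	17	22154
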