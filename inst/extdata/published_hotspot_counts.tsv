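cancer_type	n_hotspots	span_mb
GBM	839	36
BRC	759	31
LUAD	846	37
OV	990	45
HN	981	43
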