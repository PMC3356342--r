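metric	value
n_genes	8646
n_homolog_1e10	4041
n_annotated_homolog	4706
interrupted_members	296
overlapping_members	52
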