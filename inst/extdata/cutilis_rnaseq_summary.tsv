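sample_id	total	aligned	uniquely_aligned
log	117764576	71588205	65389686
stationary	152414537	88243942	80917688
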