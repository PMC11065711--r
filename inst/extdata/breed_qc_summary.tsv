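breed	n_samples	snps_total	snps_pass	pass_pct
KF	96	777962	670564	86.20
SG	32	777962	644326	82.82
BM	23	777962	666111	85.62
BR	16	777962	615444	79.10
HF	60	777962	576441	74.10
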