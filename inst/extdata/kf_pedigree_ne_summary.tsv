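breed	ne_ci	ne_ci_se	ne_fi
KF	78.56	2.40	119.15
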