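G0001	1
G0002	1
G0003	1
G0004	1
G0005	1
G0006	1
G0007	1
G0008	1
G0009	1
G0010	1
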