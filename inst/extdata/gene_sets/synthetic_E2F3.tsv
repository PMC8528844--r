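G0191	1
G0192	1
G0193	1
G0194	1
G0195	1
G0196	1
G0197	1
G0198	1
G0199	1
G0200	1
G0201	1
G0202	1
G0203	1
G0204	1
G0205	1
G0206	1
G0207	1
G0208	1
G0209	1
G0210	1
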