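G0081	1
G0082	1
G0083	1
G0084	1
G0085	1
G0086	1
G0087	1
G0088	1
G0089	1
G0090	1
G0091	1
G0092	1
G0093	1
G0094	1
G0095	1
G0096	1
G0097	1
G0098	1
G0099	1
G0100	1
G0101	1
G0102	1
G0103	1
G0104	1
G0105	1
G0106	1
G0107	1
G0108	1
G0109	1
G0110	1
G0111	1
G0112	1
G0113	1
G0114	1
G0115	1
G0116	1
G0117	1
G0118	1
G0119	1
G0120	1
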