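G0121	-1
G0122	-1
G0123	-1
G0124	-1
G0125	-1
G0126	-1
G0127	-1
G0128	-1
G0129	-1
G0130	-1
G0131	-1
G0132	-1
G0133	-1
G0134	-1
G0135	-1
G0136	-1
G0137	-1
G0138	-1
G0139	-1
G0140	-1
G0141	1
G0142	1
G0143	1
G0144	1
G0145	1
G0146	1
G0147	1
G0148	1
G0149	1
G0150	1
G0151	1
G0152	1
G0153	1
G0154	1
G0155	1
G0156	1
G0157	1
G0158	1
G0159	1
G0160	1
G0161	1
G0162	1
G0163	1
G0164	1
G0165	1
G0166	1
G0167	1
G0168	1
G0169	1
G0170	1
G0171	1
G0172	1
G0173	1
G0174	1
G0175	1
G0176	1
G0177	1
G0178	1
G0179	1
G0180	1
G0181	1
G0182	1
G0183	1
G0184	1
G0185	1
G0186	1
G0187	1
G0188	1
G0189	1
G0190	1
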