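G0011	1
G0012	1
G0013	1
G0014	1
G0015	1
G0016	1
G0017	1
G0018	1
G0019	1
G0020	1
G0021	1
G0022	1
G0023	1
G0024	1
G0025	1
G0026	1
G0027	1
G0028	1
G0029	1
G0030	1
G0031	1
G0032	1
G0033	1
G0034	1
G0035	1
G0036	1
G0037	1
G0038	1
G0039	1
G0040	1
G0041	1
G0042	1
G0043	1
G0044	1
G0045	1
G0046	1
G0047	1
G0048	1
G0049	1
G0050	1
G0051	1
G0052	1
G0053	1
G0054	1
G0055	1
G0056	1
G0057	1
G0058	1
G0059	1
G0060	1
G0061	1
G0062	1
G0063	1
G0064	1
G0065	1
G0066	1
G0067	1
G0068	1
G0069	1
G0070	1
G0071	1
G0072	1
G0073	1
G0074	1
G0075	1
G0076	1
G0077	1
G0078	1
G0079	1
G0080	1
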