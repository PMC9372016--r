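ligand	receptor
gene0001	gene0002
gene0003	gene0004
gene0005	gene0006
gene0007	gene0008
gene0009	gene0010
gene0011	gene0012
gene0013	gene0014
gene0015	gene0016
gene0017	gene0018
gene0019	gene0020
gene0021	gene0022
gene0023	gene0024
gene0025	gene0026
gene0027	gene0028
gene0029	gene0030
gene0031	gene0032
gene0033	gene0034
gene0035	gene0036
gene0037	gene0038
gene0039	gene0040
gene0041	gene0042
gene0043	gene0044
gene0045	gene0046
gene0047	gene0048
gene0049	gene0050
gene0051	gene0052
gene0053	gene0054
gene0055	gene0056
gene0057	gene0058
gene0059	gene0060
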