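#SampleID	env_biome	description
S0001	animal	synthetic sample
S0002	animal	synthetic sample
S0003	animal	synthetic sample
S0004	environment	synthetic sample
S0005	environment	synthetic sample
S0006	environment	synthetic sample
S0007	environment	synthetic sample
S0008	animal	synthetic sample
S0009	environment	synthetic sample
S0010	environment	synthetic sample
S0011	environment	synthetic sample
S0012	animal	synthetic sample
S0013	environment	synthetic sample
S0014	animal	synthetic sample
S0015	environment	synthetic sample
S0016	animal	synthetic sample
S0017	environment	synthetic sample
S0018	animal	synthetic sample
S0019	environment	synthetic sample
S0020	environment	synthetic sample
S0021	environment	synthetic sample
S0022	animal	synthetic sample
S0023	animal	synthetic sample
S0024	environment	synthetic sample
S0025	environment	synthetic sample
S0026	animal	synthetic sample
S0027	environment	synthetic sample
S0028	environment	synthetic sample
S0029	environment	synthetic sample
S0030	environment	synthetic sample
S0031	environment	synthetic sample
S0032	animal	synthetic sample
S0033	environment	synthetic sample
S0034	environment	synthetic sample
S0035	environment	synthetic sample
S0036	environment	synthetic sample
S0037	environment	synthetic sample
S0038	animal	synthetic sample
S0039	environment	synthetic sample
S0040	animal	synthetic sample
S0041	environment	synthetic sample
S0042	environment	synthetic sample
S0043	animal	synthetic sample
S0044	animal	synthetic sample
S0045	animal	synthetic sample
S0046	environment	synthetic sample
S0047	environment	synthetic sample
S0048	animal	synthetic sample
S0049	environment	synthetic sample
S0050	animal	synthetic sample
S0051	environment	synthetic sample
S0052	environment	synthetic sample
S0053	environment	synthetic sample
S0054	environment	synthetic sample
S0055	animal	synthetic sample
S0056	environment	synthetic sample
S0057	animal	synthetic sample
S0058	animal	synthetic sample
S0059	environment	synthetic sample
S0060	environment	synthetic sample
S0061	environment	synthetic sample
S0062	animal	synthetic sample
S0063	animal	synthetic sample
S0064	environment	synthetic sample
S0065	environment	synthetic sample
S0066	animal	synthetic sample
S0067	environment	synthetic sample
S0068	environment	synthetic sample
S0069	environment	synthetic sample
S0070	environment	synthetic sample
S0071	animal	synthetic sample
S0072	environment	synthetic sample
S0073	animal	synthetic sample
S0074	animal	synthetic sample
S0075	environment	synthetic sample
S0076	environment	synthetic sample
S0077	environment	synthetic sample
S0078	environment	synthetic sample
S0079	environment	synthetic sample
S0080	animal	synthetic sample
S0081	environment	synthetic sample
S0082	environment	synthetic sample
S0083	animal	synthetic sample
S0084	animal	synthetic sample
S0085	environment	synthetic sample
S0086	animal	synthetic sample
S0087	environment	synthetic sample
S0088	environment	synthetic sample
S0089	environment	synthetic sample
S0090	environment	synthetic sample
S0091	environment	synthetic sample
S0092	animal	synthetic sample
S0093	environment	synthetic sample
S0094	environment	synthetic sample
S0095	environment	synthetic sample
S0096	environment	synthetic sample
S0097	animal	synthetic sample
S0098	environment	synthetic sample
S0099	environment	synthetic sample
S0100	animal	synthetic sample
S0101	environment	synthetic sample
S0102	animal	synthetic sample
S0103	environment	synthetic sample
S0104	environment	synthetic sample
S0105	environment	synthetic sample
S0106	animal	synthetic sample
S0107	environment	synthetic sample
S0108	environment	synthetic sample
S0109	environment	synthetic sample
S0110	animal	synthetic sample
S0111	animal	synthetic sample
S0112	environment	synthetic sample
S0113	animal	synthetic sample
S0114	environment	synthetic sample
S0115	environment	synthetic sample
S0116	environment	synthetic sample
S0117	environment	synthetic sample
S0118	animal	synthetic sample
S0119	environment	synthetic sample
S0120	environment	synthetic sample
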