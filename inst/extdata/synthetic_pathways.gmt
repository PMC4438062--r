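cancer_core_synthetic	synthetic: metastatic-effect genes of the bundled scenario	g00001	g00053	g00104	g00156	g00208	g00259	g00311	g00363	g00415	g00466	g00518	g00570	g00621	g00673	g00725	g00776	g00828	g00880	g00931	g00983	g01035	g01086	g01138	g01190	g01242	g01293	g01345	g01397	g01448	g01500
wnt_like_synthetic	synthetic: up-regulated metastatic-effect genes plus passage-confounded genes	g00001	g00053	g00104	g00156	g00208	g00259	g00311	g00363	g00415	g00466	g00002	g00021	g00040	g00059	g00078	g00097	g00116	g00135
unrelated_synthetic	synthetic: genes with no injected effect	g00003	g00017	g00029	g00041	g00053	g00067	g00079	g00091	g00103	g00115
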