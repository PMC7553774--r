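synthetic_up_cluster2	up	gene_0001	gene_0002	gene_0003	gene_0004	gene_0005	gene_0006	gene_0007	gene_0008	gene_0009	gene_0010	gene_0011	gene_0012	gene_0013	gene_0014	gene_0015	gene_0016	gene_0017	gene_0018	gene_0019	gene_0020
synthetic_neutral	neutral	gene_0101	gene_0102	gene_0103	gene_0104	gene_0105	gene_0106	gene_0107	gene_0108	gene_0109	gene_0110
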