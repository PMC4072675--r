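rsid	chrom	pos	allele_a	allele_b	risk_allele
rs6687758	1	222164948	A	G	G
rs10936599	3	169492101	C	T	C
rs12657484	5	134503751	G	A	G
rs11525793	7	15648935	A	G	A
rs10505477	8	128407443	C	T	T
rs6983267	8	128413305	T	C	C
rs7014346	8	128424792	A	G	A
rs7466603	9	94483198	G	A	G
rs10795668	10	8701219	C	T	C
rs1338565	10	44059676	A	G	A
rs1665645	10	118487954	T	C	T
rs3802842	11	111171709	G	A	A
rs4631962	12	4373132	C	T	T
rs4444235	14	54410919	C	T	C
rs4779584	15	32994756	A	G	A
rs9929218	16	68820946	G	A	G
rs4939827	18	46453463	C	T	T
rs10404811	19	58154807	A	G	G
rs961253	20	6404281	G	A	A
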