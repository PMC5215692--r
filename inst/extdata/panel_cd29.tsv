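snp_id	chrom_band	locus_id	gene_label	risk_allele	other_allele
rs7517847	1p31.3	1p31.3	IL23R	T	G
rs11209026	1p31.3	1p31.3	IL23R	G	A
rs2797685	1p36.23	1p36.23	PER3	A	G
rs3024505	1q32.1	1q32.1	IL10	A	G
rs10495903	2p21	2p21	THADA	T	C
rs780093	2p23.3	2p23.3	GCKR	T	C
rs2241880	2q37.1	2q37.1	ATG16L1	G	A
rs9858542	3p21.31	3p21.31	BSN	A	G
rs3197999	3p21.31	3p21.31	MST1	A	G
rs2631367	5q31	5q31	SLC22A4	C	G
rs1050152	5q31	5q31	SLC22A5	T	C
rs11739135	5q31	5q31	IGR2198	C	G
rs1521868	5q31	5q31	IGR2196	T	G
rs1000113	5q33.1	5q33.1	IRGM	T	C
rs4958847	5q33.1	5q33.1	IRGM	A	G
rs9268832	6p21	6p21	MHC	T	C
rs6930777	6p21	6p21	MHC	A	G
rs9267798	6p21	6p21	MHC	G	A
rs212388	6q25.3	6q25.3	TAGAP	C	T
rs4263839	9q32	9q32	TNFSF15	A	G
rs10761659	10q21.2	10q21.2	ZNF365	A	G
rs150550	10q22.3	10q22.3	ZMIZ1	A	C
rs11190140	10q24.2	10q24.2	NKX2/3	T	C
rs2066844	16q12.1	16q12.1	NOD2	T	C
rs2066845	16q12.1	16q12.1	NOD2	C	G
rs2066847	16q12.1	16q12.1	NOD2	C	G
rs2542151	18p11.21	18p11.21	PTPN2	G	T
rs713875	22q12.2	22q12.2	MTMR3	C	G
rs2413583	22q13.1	22q13.1	MAP3K7IP1	C	T
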