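chrom	pos	change_cdna	change_protein	rsid	effect_term	gene	n_cases	coverage_mean	coverage_sd
2	84897501	c.6356A>G	p.Tyr2119Cys	rs17025409	missense_variant	DNAH6	17	146	18.08
2	84932720	c.8576A>G	p.Lys2859Arg	rs61750773	missense_variant	DNAH6	19	146	20.02
2	85059227	c.1034C>T	p.Arg345His	rs61744273	missense_variant	TRABD2A	18	287	42.23
5	79950724	c.181G>C	p.Ala60Pro	rs2001675	missense_variant	MSH3	15	145	57.73
6	36168628	c.529A>G	p.Ser177Gly	rs45504893	missense_variant	BRPF3	22	320	44.1
9	69391207	c.715G>A	p.Ala239Thr	.	missense_variant	ANKRD20A4	13	125	8.03
11	1017471	c.5330G>A	p.Gly1777Asp	.	missense_variant	MUC6	13	448	194.38
11	1017504	c.5297C>T	p.Thr1766Ile	.	missense_variant	MUC6	31	448	147.15
14	57755564	c.1435G>A	p.Ala479Thr	rs35759976	missense_variant	AP5M1	22	179	14.19
16	25239809	c.782G>A	p.Arg261Gln	rs111840156	missense_variant	AQP8	13	265	24.69
16	84902483	c.880A>T	p.Met294Leu	rs72799568	missense_variant	CRISPLD2	21	247	145.71
16	88902199	c.692C>G	p.Ala237Gly	rs34745339	structural_interaction_variant&missense_variant	GALNS	20	214	33.02
17	71232990	c.1369C>A	p.Arg457Ser	rs61729639	missense_variant	SPEP1	14	180	38.16
22	17450929	c.841G>A	p.Ala281Thr	rs61741409	missense_variant	GAB4	14	236	36.89
22	17450952	c.818T>C	p.Leu273Pro	rs11703655	missense_variant	GAB4	14	236	43.66
22	25024326	c.1534G>A	p.Val512Ile	.	structural_interaction_variant&missense_variant	GGT1	14	112	17.48
22	35802661	c.539C>G	p.Thr180Ser	rs2307340	missense_variant	MCM5	20	309	92.27
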