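interaction	host_run	parasite_run	replicate	processed	unique_host	multi_host	unique_parasite	multi_parasite	two_side	unmapped
Arabidopsis-Cuscuta	SRR22559142	SRR12763776	1	33950197	18572122	330452	12965830	1211131	1709	868953
Arabidopsis-Cuscuta	SRR22559143	SRR12763787	2	34443118	18046908	1526290	12979800	1178915	13583	697622
Arabidopsis-Cuscuta	SRR22559144	SRR12763788	3	36166552	20227851	337908	13292023	1260436	2831	1045503
Solanum-Cuscuta	SRR25558913	SRR12763776	1	56216612	35261137	452535	13019757	1396199	8192	6078792
Solanum-Cuscuta	SRR25558914	SRR12763787	2	54856932	35013923	490718	13016735	1307742	7000	5020814
Solanum-Cuscuta	SRR25558915	SRR12763788	3	62779945	40262060	575318	13335341	1415630	8307	7183289
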