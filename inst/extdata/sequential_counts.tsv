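interaction	host_run	parasite_run	replicate	order	processed	unique_host	multi_host	unique_parasite	multi_parasite	unmapped
Arabidopsis-Cuscuta	SRR22559142	SRR12763776	1	host_first	33950197	18603604	410240	12948080	1165669	822604
Arabidopsis-Cuscuta	SRR22559143	SRR12763787	2	host_first	34443118	18102724	1618200	12953498	1126992	641704
Arabidopsis-Cuscuta	SRR22559144	SRR12763788	3	host_first	36166552	20268051	426377	13270916	1208650	992558
Arabidopsis-Cuscuta	SRR22559142	SRR12763776	1	parasite_first	33950197	18564026	327509	12992108	1243959	822595
Arabidopsis-Cuscuta	SRR22559143	SRR12763787	2	parasite_first	34443118	17553088	752222	13639241	1857011	641556
Arabidopsis-Cuscuta	SRR22559144	SRR12763788	3	parasite_first	36166552	20210535	324911	13331684	1306968	992454
Solanum-Cuscuta	SRR25558913	SRR12763776	1	host_first	56216612	35405921	495390	13001831	1292197	6021273
Solanum-Cuscuta	SRR25558914	SRR12763787	2	host_first	54856932	35128009	538023	12993036	1226568	4971296
Solanum-Cuscuta	SRR25558915	SRR12763788	3	host_first	62779945	40372884	625278	13314939	1321988	7144856
Solanum-Cuscuta	SRR25558913	SRR12763776	1	parasite_first	56216612	35253494	441975	13066350	1433890	6020903
Solanum-Cuscuta	SRR25558914	SRR12763787	2	parasite_first	54856932	35008504	485523	13052054	1339693	4971158
Solanum-Cuscuta	SRR25558915	SRR12763788	3	parasite_first	62779945	40238892	562252	13378826	1454850	7145125
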