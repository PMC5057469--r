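family	species	accession	specimen_id	origin	genome_size_bp	gc_pct	protein_coding_genes	orfs	trna	tmrna	rrna	ncrna	introns
Scinaiaceae	Nothogenia fastigiata	SAMEA4358435	J.0141	Chile	182457	33.0	193	8	30	1	3	1	2
Scinaiaceae	Scinaia undulata	SAMEA4478602	J.0081	Chile	183795	35.9	197	9	31	1	3	1	2
Galaxauraceae	Actinotrichia fragilis	SAMEA4357171	HV04073	Philippines	183324	29.8	197	9	31	1	3	1	2
Galaxauraceae	Galaxaura rugosa	SAMEA4357173	JFC0074	Australia	181215	29.6	197	7	31	1	3	1	2
Galaxauraceae	Tricleocarpa cylindrica	SAMEA4478608	J.0145	Costa Rica	>=150119	-	>=149	>=8	>=25	>=1	>=1	>=1	>=0
Galaxauraceae	Dichotomaria marginata	SAMEA4357172	HV04060	Philippines	184395	28.8	197	11	31	1	3	1	2
Liagoraceae	Liagora brachyclada	SAMEA4395348	J.0126	Chile	182937	33.7	195	9	31	1	3	1	2
Liagoraceae	Liagora harveyana	SAMEA4358432	J.0237	Chile	182933	33.9	195	10	31	1	3	1	2
Liagoraceae	Izziella formosana	SAMEA4358392	J.0158	Costa Rica	183248	35.0	195	9	31	1	3	1	2
Liagoraceae	Neoizziella asiatica	SAMEA4358434	J.0154	Costa Rica	183313	33.4	195	10	31	1	3	1	2
Liagoraceae	Titanophycus setchellii	SAMEA4478603	J.0604	Japan	>=183356	-	195	>=9	>=31	>=1	>=3	>=1	>=2
Liagoraceae	Helminthora furcellata	SAMEA4393237	J.0165	South Africa	184585	32.1	195	8	31	1	3	1	2
Liagoraceae	Trichogloeopsis pedicellata	SAMEA4358437	C.0024	French West Indies	183497	31.9	194	8	31	1	3	1	2
Liagoraceae	Hommersandiophycus borowitzkae	SAMEA4358391	HV00480	Jamaica	184728	32.2	194	9	31	1	3	1	2
Liagoraceae	Dermonema virens	SAMEA4357169	J.0258	Taiwan	184997	34.1	195	9	31	1	3	1	2
Liagoraceae	Helminthocladia australis	SAMEA4358292	J.0167	South Africa	185694	32.8	195	9	31	1	3	1	2
Yamadaellaceae	Yamadaella caenomyce	SAMEA4358436	J.0255	Chile	182460	35.9	194	9	31	1	3	1	2
Liagoropsidaceae	Liagoropsis maxima	SAMEA4358433	J.0256	Taiwan	189564	32.1	195	11	31	1	3	1	2
Nemaliaceae	Nemalion sp.	SAMEA4478604	H.1444	Italy	182930	35.5	194	7	31	1	3	1	2
Palmariaceae	Palmaria palmata	SAMEA4478605	ODC1024	France	>=187103	-	>=196	>=11	>=31	>=1	>=3	>=1	>=2
Rhodothamniellaceae	Rhodothamniella floridula	SAMEA4478606	HEC15602	France	>=182494	-	>=196	>=9	>=29	>=1	>=1	>=1	>=2
Acrochaetiaceae	Acrochaetium secundatum	SAMEA4393238	FS1067	Bulgaria	>=183541	-	>=196	>=12	>=29	>=1	>=0	>=1	>=2
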