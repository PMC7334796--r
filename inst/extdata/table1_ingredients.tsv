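id	name	herb	mw	alogp	nhdon	nhacc	ob	dl
CR1	Poriferasta-7,22E-dien-3beta-ol	CR					42.98	0.76
CR2	2-methoxyfuranodiene	CR					53.58	0.13
CR5	EIC	CR					41.9	0.14
CR14	Methyl linoleate	CR					41.93	0.17
CR16	(+/-)-Isoborneol	CR					86.98	0.05
CR21	Perlolyrine	CR					65.95	0.27
CR28	DIOP	CR					43.59	0.39
CR32	ZINC03978781	CR					43.83	0.76
CR37	Stigmasterol	CR					43.83	0.76
CR38	Syringin	CR					14.64	0.32
CR43	Tectorigenin	CR					28.41	0.27
CR45	7-Methoxy-2-methyl isoflavone	CR					42.56	0.2
CR48	Spinasterol	CR					42.98	0.76
CR49	Atractylenolide II	CR					47.5	0.15
CR52	Atractylenolide III	CR					68.11	0.17
CR61	Frutinone A	CR					65.9	0.34
CR63	Luteolin	CR					36.16	0.25
CR67	Taraxerol	CR					38.4	0.77
CR69	Stigmast-7-enol	CR					37.42	0.75
CR70	Norharman	CR					18.88	0.08
CR73	3-Beta-hydroxymethyllenetanshiquinone	CR					32.16	0.41
CR75	HMF	SHARED					45.07	0.02
CR76	Methyl icosa-11,14-dienoate	CR					39.67	0.23
CR77	Apigenin	SHARED					23.06	0.21
CR81	(1R)-2,3,4,9-Tetrahydro-1H-pyrido[3,4-b]indol-2-ium-1-carboxylate	CR					52.9	0.13
CR97	5-Alpha-stigmastan-3,6-dione	CR					33.12	0.79
CR99	7-(Beta-xylosyl)cephalomannine_qt	CR					38.33	0.29
CR101	Codonopsine	CR					45.83	0.13
CR103	Daturilin	CR					50.37	0.77
CR106	Glycitein	CR					50.48	0.24
CR112	Spinoside A	CR					39.97	0.4
CR113	(8S,9S,10R,13R,14S,17R)-17-[(E,2R,5S)-5-ethyl-6-methylhept-3-en-2-yl]-10,13-dimethyl-1,2,4,7,8,9,11,12,14,15,16,17-dodecahydrocyclopenta[a]phenanthren-3-one	CR					45.4	0.76
CR117	11-Hydroxyrankinidine	CR					40	0.66
CR123	Ethyl-beta-D-fructofuranoside	CR					33.84	0.15
CR130	Furanodiene	CR					45.11	0.1
CR132	(+)-Beta-pinene	CR					44.77	0.05
ATR3	Vanillic acid	ATR					35.47	0.04
ATR6	(-)-Alloaromadendrene	ATR					54.04	0.1
ATR12	Calarene	ATR					52.16	0.11
ATR15	p-MCA	ATR					31	0.05
ATR19	Marmesin	ATR					50.28	0.18
ATR20	Majudin	ATR					42.21	0.13
ATR23	(-)-Caryophyllene oxide	ATR					32.67	0.13
ATR28	beta-Asarone	ATR					35.61	0.06
ATR30	beta-Gurjunene	ATR					51.36	0.1
ATR35	beta-Cubebene	ATR					32.81	0.11
ATR40	2'-O-Methylisoliquiritigenin	ATR					75.86	0.17
ATR50	(+)-Ledene	ATR					51.84	0.1
ATR53	(+)-alpha-Longipinene	ATR					57.47	0.12
ATR54	8-Isopentenyl-kaempferol	ATR					38.04	0.39
ATR55	Aminacrine	ATR					35	0.12
ATR57	Aristolene	ATR					52.2	0.11
ATR58	Aristolone	ATR					45.31	0.13
ATR59	Azaron	ATR					38.39	0.06
ATR63	Bisasarcin	ATR					18.55	0.5
ATR65	Calamendiol	ATR					61.13	0.11
ATR73	Isocalamendiol	ATR					57.63	0.11
ATR78	Longicyclene	ATR					46.07	0.15
ATR79	Murolan-3,9(11)-diene-10-peroxy	ATR					36.72	0.11
ATR81	Patchoulene	ATR					49.06	0.11
ATR84	Spathulenol	ATR					81.61	0.12
ATR87	alpha-Gurjunene	ATR					52.57	0.1
ATR88	alpha-Panasinsene	ATR					56.77	0.12
ATR89	(1R,3aS,4R,6aS)-1,4-bis(3,4-dimethoxyphenyl)-1,3,3a,4,6,6a-hexahydrofuro[4,3-c]furan	ATR					52.35	0.62
ATR91	Cycloartenol	ATR					38.69	0.78
ATR93	Kaempferol	ATR					41.88	0.24
ATR98	(-)-alpha-Cedrene	ATR					55.56	0.1
ATR102	p-Coumaric acid	ATR					43.29	0.04
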