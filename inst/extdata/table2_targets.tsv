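gene	name	uniprot
ABCA1	ATP-binding cassette subfamily A member 1	O95477
ABCB1	Multidrug resistance protein 1	P08183
ACHE	Acetylcholinesterase	P22303
ADH1C	Alcohol dehydrogenase 1C	P00326
ADRA2C	Alpha-2C adrenergic receptor	P18825
ADRB2	Beta-2 adrenergic receptor	P07550
AHR	Aryl hydrocarbon receptor	P35869
ALOX5	Arachidonate 5-lipoxygenase	P09917
APP	Amyloid beta A4 protein	P05067
BACE1	Beta-secretase 1	P56817
BAX	Apoptosis regulator BAX	Q07812
BCHE	Cholinesterase	P06276
BCL2	Apoptosis regulator Bcl-2	P10415
CALM1	Calmodulin	P0DP23
CASP3	Caspase-3	P42574
CASP7	Caspase-7	P55210
CDK5	Cyclin-dependent kinase 5 (CDK5)	Q00535
CHRM1	Muscarinic acetylcholine receptor M1	P11229
CHRM2	Muscarinic acetylcholine receptor M2	P08172
CHRM3	Muscarinic acetylcholine receptor M3	P20309
CHRNA2	Neuronal acetylcholine receptor subunit alpha-2	Q15822
CHRNA7	Neuronal acetylcholine receptor protein, alpha-7 chain	P36544
CHUK	Inhibitor of NF-kappa-B kinase (IKK)	O15111
CYP1A2	Cytochrome P450 1A2	P05177
CYP2A6	Cytochrome P450 2A6	P11509
CYP2D6	Cytochrome P450 2D6 (2D6)	P10635
CYP3A4	Cytochrome P450 3A4	P08684
DIO1	Type I iodothyronine deiodinase	P49895
ESR1	Estrogen receptor	P03372
F2	Thrombin	P00734
F7	Coagulation factor VII	P08709
FLT3	Tyrosine-protein kinase receptor FLT3	P36888
GABRA1	Gamma-aminobutyric acid receptor subunit alpha-1	P14867
GABRA2	Gamma-aminobutyric-acid receptor alpha-2 subunit	P47869
GABRA5	Gamma-aminobutyric-acid receptor alpha-5 subunit	P31644
GSK3B	Glycogen synthase kinase-3 beta	P49841
HMOX1	Heme oxygenase 1	P09601
HTR2A	5-Hydroxytryptamine 2A receptor	P28223
IGF1R	Insulin-like growth factor 1 receptor	P08069
IKBKB	Inhibitor of nuclear factor kappa-B kinase subunit beta	O14920
IL10	Interleukin-10	P22301
IL1B	Interleukin-1 beta	P01584
INS	Insulin	P01308
INSR	Insulin receptor	P06213
KDR	Vascular endothelial growth factor receptor 2	P35968
MAOA	Amine oxidase [flavin-containing] A	P21397
MAOB	Amine oxidase [flavin-containing] B	P27338
MAPK10	Mitogen-activated protein kinase 10	P53779
MET	Hepatocyte growth factor receptor	P08581
NOS3	Nitric-oxide synthase, endothelial	P29474
NR1I2	Nuclear receptor subfamily 1 group I member 2	O75469
PLAU	Urokinase-type plasminogen activator	P00749
PPARG	Peroxisome proliferator activated receptor gamma	P37231
PTGES	Prostaglandin E synthase	O14684
PTGS1	Prostaglandin G/H synthase 1	P23219
PTGS2	Prostaglandin G/H synthase 2	P35354
RXRA	Retinoic acid receptor RXR-alpha	P19793
RXRG	Retinoic acid receptor RXR-gamma	P48443
SLC2A4	Solute carrier family 2, facilitated glucose transporter member 4	P14672
SOAT1	Acyl-cholesterol acyltransferase 1	P35610
TNF	Tumor necrosis factor	P01375
VEGFA	Vascular endothelial growth factor A	P15692
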