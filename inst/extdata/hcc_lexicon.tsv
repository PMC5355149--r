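symbol	gene_id	description	aliases
VEGFA	7422	vascular endothelial growth factor A	VEGF-A
AFP	174	alpha fetoprotein	
CDH1	999	cadherin 1 (E-cadherin)	E-cadherin
MMP2	4313	matrix metallopeptidase 2	
MMP9	4318	matrix metallopeptidase 9	
MAPK1	5594	mitogen-activated protein kinase 1	ERK2
TGFB1	7040	transforming growth factor beta 1	TGF-beta1
AKT1	207	AKT serine/threonine kinase 1	
CTNNB1	1499	catenin beta 1	beta-catenin
PTK2	5747	protein tyrosine kinase 2 (FAK)	FAK
SPP1	6696	secreted phosphoprotein 1	osteopontin
NME1	4830	NME/NM23 nucleoside diphosphate kinase 1	NM23
NFKB1	4790	nuclear factor kappa B subunit 1	
MET	4233	MET proto-oncogene, receptor tyrosine kinase	
BSG	682	basigin (CD147)	CD147
PIK3CA	5290	phosphatidylinositol-4,5-bisphosphate 3-kinase catalytic subunit alpha	
HIF1A	3091	hypoxia inducible factor 1 alpha subunit	HIF-1alpha
CD44	960	CD44 molecule	
FN1	2335	fibronectin 1	fibronectin
HGF	3082	hepatocyte growth factor	
UBC	7316	ubiquitin C	
EGFR	1956	epidermal growth factor receptor	
MDM2	4193	MDM2 proto-oncogene	
TP53	7157	tumor protein p53	p53
APP	351	amyloid beta precursor protein	
HSP90AA1	3320	heat shock protein 90 alpha family class A member 1	
EP300	2033	E1A binding protein p300	p300
SUMO1	7341	small ubiquitin-like modifier 1	
GRB2	2885	growth factor receptor bound protein 2	
SRC	6714	SRC proto-oncogene, non-receptor tyrosine kinase	
YWHAZ	7534	tyrosine 3-monooxygenase/tryptophan 5-monooxygenase activation protein zeta	
ESR1	2099	estrogen receptor 1	
HSP90AB1	3326	heat shock protein 90 alpha family class B member 1	
HDAC1	3065	histone deacetylase 1	
AR	367	androgen receptor	
CUL7	9820	cullin 7	
MYC	4609	v-myc avian myelocytomatosis viral oncogene homolog	c-Myc
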