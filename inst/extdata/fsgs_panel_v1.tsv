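symbol	mode	chromosome	phenocopy
ACTN4	AD	chr19	false
INF2	AD	chr14	false
TRPC6	AD	chr11	false
ANLN	AD	chr7	false
ARHGAP24	AD	chr4	false
WT1	AD	chr11	false
PAX2	AD	chr10	false
LMX1B	AD	chr9	true
MAFB	AD	chr20	false
MYH9	AD	chr22	true
LMNA	AD	chr1	false
PODXL	AD	chr7	false
COL4A3	AD	chr2	true
COL4A4	AD	chr2	true
CD2AP	AD	chr6	false
FN1	AD	chr2	true
GATA3	AD	chr10	true
E2F3	AD	chr6	false
TRIM8	AD	chr10	false
CLCN5	XL	chrX	true
OCRL	XL	chrX	true
GLA	XL	chrX	true
COL4A5	XL	chrX	true
NXF5	XL	chrX	false
TBC1D8B	XL	chrX	false
LAGE3	XL	chrX	false
NPHS1	AR	chr19	false
NPHS2	AR	chr1	false
PLCE1	AR	chr10	false
LAMB2	AR	chr3	false
PTPRO	AR	chr12	false
MYO1E	AR	chr15	false
ITGB4	AR	chr17	false
ITGA3	AR	chr17	false
CD151	AR	chr11	false
CUBN	AR	chr10	false
COQ2	AR	chr4	false
COQ4	AR	chr9	false
COQ6	AR	chr14	false
COQ8B	AR	chr19	false
PDSS1	AR	chr10	false
PDSS2	AR	chr6	false
SMARCAL1	AR	chr2	true
SGPL1	AR	chr10	false
DGKE	AR	chr17	false
CRB2	AR	chr9	false
FAT1	AR	chr4	false
KANK1	AR	chr9	false
KANK2	AR	chr19	false
KANK4	AR	chr1	false
EMP2	AR	chr16	false
ARHGDIA	AR	chr17	false
SCARB2	AR	chr4	true
ALG1	AR	chr16	true
PMM2	AR	chr16	true
TTC21B	AR	chr2	false
WDR73	AR	chr15	false
OSGEP	AR	chr14	false
TP53RK	AR	chr20	false
TPRKB	AR	chr2	false
GON7	AR	chr14	false
YRDC	AR	chr1	false
GAPVD1	AR	chr9	false
NUP85	AR	chr17	false
NUP93	AR	chr16	false
NUP107	AR	chr12	false
NUP133	AR	chr1	false
NUP160	AR	chr11	false
NUP205	AR	chr7	false
XPO5	AR	chr6	false
AVIL	AR	chr12	false
MAGI2	AR	chr7	false
TNS2	AR	chr12	false
DLC1	AR	chr8	false
CDK20	AR	chr9	false
ITSN1	AR	chr21	false
ITSN2	AR	chr2	false
NOS1AP	AR	chr1	false
APOL1	AR	chr22	false
DAAM2	AR	chr6	false
LCAT	AR	chr16	true
ZMPSTE24	AR	chr1	true
CFH	AR	chr1	true
MYO9A	AR	chr15	false
CTNS	AR	chr17	true
MMACHC	AR	chr1	true
NEU1	AR	chr6	true
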