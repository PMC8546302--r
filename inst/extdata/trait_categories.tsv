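code	category
200KW	agronomic
25%G	agronomic
50%G	agronomic
75%G	agronomic
AGB	agronomic
BDT	quality
BM	agronomic
BY	agronomic
CDMA	agronomic
CID	agronomic
DA	agronomic
DDT	quality
DGC	quality
DH	agronomic
DPM	agronomic
DST	quality
DTF	agronomic
FFD	quality
FLH	agronomic
FWA	quality
GAS	agronomic
GCuC	micronutrient
GFD	agronomic
GFeC	micronutrient
GFR	agronomic
GL	agronomic
GL/GW	agronomic
GMnC	micronutrient
GN	agronomic
GPC	quality
GPL	agronomic
GSeC	micronutrient
GW	agronomic
GWe	agronomic
GWs	agronomic
GY	agronomic
GZnC	micronutrient
HI	agronomic
HW	quality
KH	quality
KL	agronomic
KW	agronomic
LDMA	agronomic
LL	agronomic
LS	agronomic
LW	agronomic
LY	agronomic
MDR	agronomic
MRS	agronomic
MTI	quality
NG	agronomic
PDMA	agronomic
PGMS	agronomic
PH	agronomic
PLH	agronomic
PT	agronomic
SD	agronomic
SDS	quality
SHS	agronomic
SHZnC	micronutrient
SL	agronomic
SN	agronomic
SNS	agronomic
SW	agronomic
TKW	agronomic
TMRS	agronomic
TN	agronomic
UIH	agronomic
WGC	quality
ZnE	micronutrient
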