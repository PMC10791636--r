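gene_id	expressed_allele
THAP3	Paternal
DNMT1	Paternal
SIAH1	Paternal
RHOBTB3	Paternal
CDKN1C	Maternal
KLHDC10	Maternal
ZFAT	Paternal
ADTRP	Maternal
ATP10A	Maternal
FGF12	Paternal
JMJD1C	Paternal
PCLAF	Paternal
IGF2	Paternal
H19	Maternal
MEG3	Maternal
SNRPN	Paternal
PEG3	Paternal
PEG10	Paternal
MEST	Paternal
PLAGL1	Paternal
GRB10	Maternal
KCNQ1	Maternal
KCNQ1OT1	Paternal
GNAS	Maternal
NNAT	Paternal
DLK1	Paternal
RTL1	Paternal
UBE3A	Maternal
NDN	Paternal
MKRN3	Paternal
MAGEL2	Paternal
ZIM2	Paternal
OSBPL5	Maternal
PHLDA2	Maternal
SLC22A18	Maternal
IGF2R	Maternal
AIRN	Paternal
ZDBF2	Paternal
GPR1	Maternal
NAP1L5	Paternal
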