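# Example list of mitochondrially localised genes (small curated subset for
# tests and demos; supply a full MitoCarta-style list for real analyses).
PDHA1
PDHB
PDHX
PDP1
PDPR
DLAT
DLD
CS
ACO2
IDH3A
OGDH
SUCLG1
SUCLA2
SDHA
SDHB
FH
MDH2
NDUFA9
NDUFS1
NDUFS2
NDUFV1
UQCRC1
UQCRC2
CYC1
COX4I1
COX5A
ATP5F1A
ATP5F1B
ATP5F1C
ATP5F1E
ATP5PB
VDAC1
VDAC2
TOMM20
TOMM40
TIMM23
HSPD1
HSPE1
SOD2
CAT
CPT1A
CPT2
SLC25A4
SLC25A20
SLC25A24
ACADM
ACADVL
HADHA
HADHB
ETFA
ETFB
PANK2
DGLUCY
MCCC2
PCK2
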