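gene,provenance
BIRC5,cited
BIRC3,cited
TNF,cited
BAX,synthetic_placeholder
BAK1,synthetic_placeholder
BCL2,synthetic_placeholder
BCL2L1,synthetic_placeholder
BCL2L2,synthetic_placeholder
BCL2L11,synthetic_placeholder
BID,synthetic_placeholder
BAD,synthetic_placeholder
BIK,synthetic_placeholder
BMF,synthetic_placeholder
BBC3,synthetic_placeholder
PMAIP1,synthetic_placeholder
MCL1,synthetic_placeholder
BCL2A1,synthetic_placeholder
BOK,synthetic_placeholder
HRK,synthetic_placeholder
CASP1,synthetic_placeholder
CASP2,synthetic_placeholder
CASP3,synthetic_placeholder
CASP4,synthetic_placeholder
CASP5,synthetic_placeholder
CASP6,synthetic_placeholder
CASP7,synthetic_placeholder
CASP8,synthetic_placeholder
CASP9,synthetic_placeholder
CASP10,synthetic_placeholder
CASP14,synthetic_placeholder
XIAP,synthetic_placeholder
BIRC2,synthetic_placeholder
BIRC6,synthetic_placeholder
BIRC7,synthetic_placeholder
BIRC8,synthetic_placeholder
NAIP,synthetic_placeholder
TP53,synthetic_placeholder
TP63,synthetic_placeholder
TP73,synthetic_placeholder
MDM2,synthetic_placeholder
MDM4,synthetic_placeholder
CDKN1A,synthetic_placeholder
CDKN1B,synthetic_placeholder
GADD45A,synthetic_placeholder
PERP,synthetic_placeholder
TP53BP2,synthetic_placeholder
BCL2L14,synthetic_placeholder
FAS,synthetic_placeholder
FASLG,synthetic_placeholder
TNFRSF1A,synthetic_placeholder
TNFRSF1B,synthetic_placeholder
TNFRSF10A,synthetic_placeholder
TNFRSF10B,synthetic_placeholder
TNFRSF10C,synthetic_placeholder
TNFRSF10D,synthetic_placeholder
TNFSF10,synthetic_placeholder
TNFRSF21,synthetic_placeholder
TNFRSF25,synthetic_placeholder
CD40,synthetic_placeholder
CD40LG,synthetic_placeholder
FADD,synthetic_placeholder
TRADD,synthetic_placeholder
RIPK1,synthetic_placeholder
RIPK2,synthetic_placeholder
CRADD,synthetic_placeholder
DAPK1,synthetic_placeholder
APAF1,synthetic_placeholder
CYCS,synthetic_placeholder
DIABLO,synthetic_placeholder
HTRA2,synthetic_placeholder
AIFM1,synthetic_placeholder
ENDOG,synthetic_placeholder
NOL3,synthetic_placeholder
CFLAR,synthetic_placeholder
CARD8,synthetic_placeholder
NLRP1,synthetic_placeholder
PYCARD,synthetic_placeholder
CASP8AP2,synthetic_placeholder
TRAF1,synthetic_placeholder
TRAF2,synthetic_placeholder
TRAF3,synthetic_placeholder
NFKB1,synthetic_placeholder
RELA,synthetic_placeholder
BNIP2,synthetic_placeholder
BNIP3,synthetic_placeholder
BNIP3L,synthetic_placeholder
BAG1,synthetic_placeholder
BAG3,synthetic_placeholder
BCL10,synthetic_placeholder
BCL2L10,synthetic_placeholder
TNFRSF9,synthetic_placeholder
LTA,synthetic_placeholder
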