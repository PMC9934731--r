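# Curated 59-node logic model of CAR T-cell / tumor cell interaction
# signaling (CD3zeta activating + CD28 costimulatory CAR design).
# All nodes use the default propensities pa=0.5, pd=0.05.
# Curation notes (see package documentation):
#   - the LCK rule is printed with unbalanced parentheses in the source
#     table; the packaged rule is the minimal balancing that preserves the
#     printed token sequence
#   - the perforin/granzyme B node is canonically named PERGRZB (the name
#     PERGRZM is accepted as an alias), and the inhibition readout CINHIB
#     (alias CINHI)
#   - the CFUNC rule drops the undefined symbol CDSYF and reads
#     AP1 & NFAT & MTORC1
@model cart_table1
TAex = 0, role=input, compartment=tumor
TA = TAex, compartment=tumor
IS = !CASP3CASP7, compartment=interface
SCFV = IS & TA
CD28 = SCFV & LCK
CD3zeta = LCK & CD28
LCK = !LCK & ((!SHP1 | (SHP1 & ERK)) & ((!SHP2 | (SHP2 & ERK))))
ZAP70 = CD3zeta & LCK & !(SHP1 | SHP2)
IL2ex = 0, role=input, compartment=interface
IL2 = IL2ex
IL2R = IL2
JAK13 = IL2R
PDL1L2ex = 0, role=input, compartment=tumor
PDL1L2 = PDL1L2ex
PD1ex = PDCD1ge
PD1 = IS & PDL1L2
CD8086ex = 0, role=input, compartment=tumor
CD8086 = CD8086ex
CTLA4ex = Calcium
CTLA4 = IS & CD8086 & CTLA4ex
SHP2 = PD1 | CTLA4
SHP1 = (PD1 & !SHP2) | (LCK & !ERK)
LAT = ZAP70
SLP76 = ZAP70 | LAT
PLCgamma1 = SLP76
DAG = PLCgamma1
IP3 = PLCgamma1
WASPCDC42 = SLP76
P38 = ZAP70
PKCtheta = (DAG | PDPK1) & !(SHP1 | SHP2)
PI3K = CD28 | CTLA4
PDPK1 = PI3K
AKT = PI3K & PDPK1
MTORC1 = AKT
RASGRP = DAG
GRB2SOS = LAT | JAK13 | CD28
ERK = (RASGRP | GRB2SOS) & !(SHP1 | SHP2)
Calcium = IP3
Calmodulin = Calcium
Calcineurin = Calcium & Calmodulin
CFOS = ERK | CREB
CJUN = PKCtheta | WASPCDC42
AP1 = CFOS & CJUN & !dNFAT
BATF = PD1
NFKB = PKCtheta
NFAT = Calcineurin | P38
dNFAT = (NFAT & !AP1) | (NFAT & !STAT5)
CREB = P38 | Calmodulin
STAT5 = IL2R & JAK13
IL2ge = AP1 & NFKB & NFAT
PDCD1ge = (AP1 & NFAT) | (STAT5 & NFAT)
CYTOGRAN = WASPCDC42 & PKCtheta & Calcium & PI3K
FASL = CYTOGRAN
PERGRZB = CYTOGRAN
FAS = FASL, compartment=tumor
CASP3CASP7 = FASL | PERGRZB, compartment=tumor
CFUNC = AP1 & NFAT & MTORC1, role=readout
CINHIB = dNFAT | BATF, role=readout
TAPOP = CASP3CASP7, role=readout, compartment=tumor
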