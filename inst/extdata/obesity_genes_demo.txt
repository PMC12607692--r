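# Demo obesity-associated gene set (toy extract, not a database reconstruction)
CDH4
NR3C2
ACTG1
COG5
CAT
HDAC4
FTO
DOK7
OCLN
ATXN1
LEP
LEPR
MC4R
POMC
ADIPOQ
PPARG
ABCG2
IRS1
UCP1
SIM1
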