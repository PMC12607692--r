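# Demo sleep-associated gene set (toy extract, not a database reconstruction)
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
CLOCK
PER2
PER3
ARNTL
CRY1
MTNR1B
CREM
CSNK1E
HCRTR2
ADA
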