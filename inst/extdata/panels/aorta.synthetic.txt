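# aorta: synthetic placeholder panel (27 genes).
# Replace with a curated gene list; one symbol per line.
FBN1
TGFBR1
TGFBR2
TGFB2
SMAD3
ACTA2
MYH11
COL3A1
MYLK
AORTA_01
AORTA_02
AORTA_03
AORTA_04
AORTA_05
AORTA_06
AORTA_07
AORTA_08
AORTA_09
AORTA_10
AORTA_11
AORTA_12
AORTA_13
AORTA_14
AORTA_15
AORTA_16
AORTA_17
AORTA_18
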