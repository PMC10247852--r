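# CDGP: synthetic placeholder panel (84 genes).
# Replace with a curated gene list; one symbol per line.
MYBPC3
MYH7
KCNQ1
KCNH2
SCN5A
CALM1
CALM2
CALM3
RYR2
TNNT2
TNNI3
TNNC1
LDLR
PKP2
DSP
DSG2
DSC2
LMNA
TPM1
ACTC1
CASQ2
KCNE1
KCNE2
KCNJ2
CDGP_01
CDGP_02
CDGP_03
CDGP_04
CDGP_05
CDGP_06
CDGP_07
CDGP_08
CDGP_09
CDGP_10
CDGP_11
CDGP_12
CDGP_13
CDGP_14
CDGP_15
CDGP_16
CDGP_17
CDGP_18
CDGP_19
CDGP_20
CDGP_21
CDGP_22
CDGP_23
CDGP_24
CDGP_25
CDGP_26
CDGP_27
CDGP_28
CDGP_29
CDGP_30
CDGP_31
CDGP_32
CDGP_33
CDGP_34
CDGP_35
CDGP_36
CDGP_37
CDGP_38
CDGP_39
CDGP_40
CDGP_41
CDGP_42
CDGP_43
CDGP_44
CDGP_45
CDGP_46
CDGP_47
CDGP_48
CDGP_49
CDGP_50
CDGP_51
CDGP_52
CDGP_53
CDGP_54
CDGP_55
CDGP_56
CDGP_57
CDGP_58
CDGP_59
CDGP_60
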