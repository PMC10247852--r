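# SDGP: synthetic placeholder panel (166 genes).
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
SDGP_01
SDGP_02
SDGP_03
SDGP_04
SDGP_05
SDGP_06
SDGP_07
SDGP_08
SDGP_09
SDGP_10
SDGP_11
SDGP_12
SDGP_13
SDGP_14
SDGP_15
SDGP_16
SDGP_17
SDGP_18
SDGP_19
SDGP_20
SDGP_21
SDGP_22
SDGP_23
SDGP_24
SDGP_25
SDGP_26
SDGP_27
SDGP_28
SDGP_29
SDGP_30
SDGP_31
SDGP_32
SDGP_33
SDGP_34
SDGP_35
SDGP_36
SDGP_37
SDGP_38
SDGP_39
SDGP_40
SDGP_41
SDGP_42
SDGP_43
SDGP_44
SDGP_45
SDGP_46
SDGP_47
SDGP_48
SDGP_49
SDGP_50
SDGP_51
SDGP_52
SDGP_53
SDGP_54
SDGP_55
SDGP_56
SDGP_57
SDGP_58
SDGP_59
SDGP_60
SDGP_61
SDGP_62
SDGP_63
SDGP_64
SDGP_65
SDGP_66
SDGP_67
SDGP_68
SDGP_69
SDGP_70
SDGP_71
SDGP_72
SDGP_73
SDGP_74
SDGP_75
SDGP_76
SDGP_77
SDGP_78
SDGP_79
SDGP_80
SDGP_81
SDGP_82
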