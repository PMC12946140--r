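pt,soc
pt_01,soc_1
pt_02,soc_2
pt_03,soc_3
pt_04,soc_1
pt_05,soc_2
pt_06,soc_3
pt_07,soc_1
pt_08,soc_2
pt_09,soc_3
pt_10,soc_1
pt_11,soc_2
pt_12,soc_3
pt_13,soc_1
pt_14,soc_2
pt_15,soc_3
pt_16,soc_1
pt_17,soc_2
pt_18,soc_3
pt_19,soc_1
pt_20,soc_2
pt_21,soc_3
pt_22,soc_1
pt_23,soc_2
pt_24,soc_3
pt_25,soc_1
pt_26,soc_2
pt_27,soc_3
pt_28,soc_1
pt_29,soc_2
pt_30,soc_3
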