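site	cell_1	cell_2	cell_3	cell_5	cell_6	cell_7	cell_8	cell_9	cell_12	cell_16	cell_18	cell_19	cell_20	cell_22	cell_24	cell_25	cell_26	cell_29	cell_30	cell_31	cell_36	cell_37	cell_40	cell_41	cell_43	cell_44	cell_45	cell_47	cell_48	cell_49	cell_50	cell_52	cell_54	cell_56	cell_60	cell_61	cell_63	cell_66	cell_69	cell_70	cell_72	cell_73	cell_74	cell_76	cell_78	cell_79	cell_80	cell_82	cell_86	cell_87	cell_88	cell_89	cell_90	cell_91	cell_93	cell_94	cell_97	cell_100
PDE4DIP_A>G	-	-	-	1	1	0	-	0	-	-	-	0	-	-	-	-	-	-	1	-	-	-	0	-	0	-	1	0	-	-	-	-	-	1	-	0	-	-	-	0	-	0	1	0	0	-	0	0	1	-	0	-	-	-	-	1	1	-
NTRK1_A>G	-	0	-	-	1	-	-	-	-	2	-	2	1	1	-	-	1	-	2	-	-	1	-	-	0	0	-	-	2	-	2	1	0	-	-	1	-	-	0	1	1	-	0	0	1	1	0	1	-	0	-	-	0	-	0	0	1	2
SESN2_C>T	1	1	1	-	-	-	-	1	1	1	2	-	-	1	-	-	-	0	0	1	-	2	2	-	0	2	0	1	1	1	0	0	0	1	-	1	0	1	-	-	1	0	1	2	2	-	1	1	1	2	1	0	0	1	2	2	1	1
ARHGAP5_G>A	-	1	-	-	-	0	0	2	-	-	-	-	0	1	1	-	-	-	-	0	-	1	-	-	0	-	0	0	-	1	0	-	-	0	0	-	-	0	-	1	0	0	0	-	0	0	1	1	-	0	0	-	-	0	1	0	1	0
DNAJC17_C>G	1	-	1	-	-	-	-	0	-	1	0	-	-	-	-	-	-	2	1	-	-	-	-	-	1	2	-	2	1	1	-	1	0	1	1	-	1	1	1	1	2	-	1	0	1	0	1	1	-	1	-	0	-	-	1	-	2	1
USP32_C>T	-	-	-	1	0	-	-	1	-	-	-	-	0	0	0	-	-	-	0	-	-	-	-	-	-	1	0	1	0	0	0	1	0	1	0	0	-	1	0	0	-	-	-	-	-	0	-	0	1	-	0	1	1	-	0	0	0	-
ANAPC1_G>A	-	-	-	1	0	1	0	1	-	1	0	-	1	1	0	1	1	0	2	-	0	-	-	0	0	0	0	1	-	0	0	1	-	0	-	-	0	0	1	-	0	-	0	0	-	-	-	1	0	-	0	0	-	-	-	0	-	0
RETSAT_C>T	-	0	-	1	0	0	-	-	-	0	-	-	-	0	-	0	0	-	0	-	0	-	0	-	0	-	0	0	-	1	0	1	0	-	0	1	0	0	1	0	0	-	0	1	1	-	1	0	0	-	0	0	-	1	1	0	0	-
ST13_G>A	0	0	-	-	-	-	0	1	1	1	-	0	1	-	-	1	-	-	1	0	1	1	-	0	0	1	-	1	-	-	0	1	-	1	1	1	1	1	1	0	1	-	0	-	0	1	1	0	1	1	1	0	1	1	0	-	1	0
DLEC1_T>C	-	-	-	-	-	-	-	1	-	1	-	-	0	2	2	2	-	-	1	-	-	1	-	-	-	-	2	1	1	-	-	-	2	-	2	-	-	1	-	-	-	-	2	2	0	1	-	-	-	-	-	-	-	0	2	-	-	1
FRG1_G>A	0	0	1	0	0	-	0	-	0	0	0	0	-	-	-	0	-	-	0	-	-	-	0	0	0	-	0	1	0	0	0	0	-	0	0	1	1	0	-	0	0	0	0	0	0	0	0	1	1	0	-	1	0	-	0	0	0	0
DMXL1_G>A	2	-	-	1	-	0	-	1	-	2	-	-	-	2	-	0	0	1	1	-	2	-	1	-	0	-	-	-	-	1	-	1	-	1	1	0	0	1	-	1	-	-	-	-	2	-	-	-	0	-	-	0	-	1	-	0	2	-
FAM115C_T>C	-	-	-	-	0	-	-	-	-	-	-	0	-	-	-	-	0	-	-	-	-	-	-	-	-	2	0	0	-	-	-	-	-	1	-	-	-	-	-	-	-	-	0	-	1	-	-	-	-	0	-	1	-	-	-	-	-	-
MLL3_C>T	-	-	0	-	0	0	-	0	0	0	1	-	0	-	0	-	0	0	1	0	1	1	0	-	0	0	0	-	-	0	1	1	1	-	1	0	-	0	-	0	-	0	0	-	-	0	0	0	0	0	-	0	0	-	1	-	-	0
ABCB5_G>T	1	-	-	1	-	-	1	2	1	0	1	-	-	0	0	-	-	2	2	-	-	2	-	-	-	-	1	-	-	-	-	-	-	1	1	1	-	1	0	0	-	-	1	0	-	1	0	-	1	-	-	1	-	-	-	-	0	-
ASNS_T>A	0	0	0	0	0	0	0	1	-	0	0	0	-	0	0	1	1	0	-	0	1	1	1	-	0	1	0	-	0	-	1	-	0	-	1	-	-	0	-	0	0	-	0	0	1	0	1	0	0	0	0	0	0	0	-	-	1	0
PABPC1_C>T	0	0	0	0	0	0	0	-	1	-	0	-	-	0	0	0	-	-	0	0	-	0	0	-	1	0	-	0	0	0	0	0	0	-	0	-	0	0	0	0	-	-	0	-	0	-	0	1	0	0	-	0	-	0	1	-	0	0
TOP1MT_A>G	-	-	-	-	-	-	-	-	-	-	-	0	-	-	-	-	-	-	-	0	2	2	1	-	-	1	-	1	-	1	2	-	2	2	0	-	-	-	-	1	-	1	-	1	-	-	1	2	-	-	-	-	2	1	-	0	-	1
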