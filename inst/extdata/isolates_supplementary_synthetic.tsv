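isolate_id	guide_id	genotype	mutations
sg2_01	sgRNA2	WT	293C>T
sg2_02	sgRNA2	WT	296C>T
sg2_03	sgRNA2	WT	299C>T
sg2_04	sgRNA2	WT	293C>T
sg2_05	sgRNA2	WT	296C>T
sg2_06	sgRNA2	WT	302C>T
sg2_07	sgRNA2	WT	291C>G
sg2_08	sgRNA2	WT	299C>G
sg2_09	sgRNA2	WT	296C>A
sg2_10	sgRNA2	WT	305C>A
sg2_11	sgRNA2	WT	308A>G
sg2_12	sgRNA2	WT	294T>A
sg2_13	sgRNA2	WT	297del
sg2_14	sgRNA2	WT	300–301del
sg2_15	sgRNA2	WT	285G>A
sg2_16	sgRNA2	WT	315G>T
sg2_17	sgRNA2	WT	102A>C
sg2_18	sgRNA2	WT	455C>A
sg2_19	sgRNA2	WT	723C>A
sg2_20	sgRNA2	WT	1203G>A
sg2_21	sgRNA2	WT	1544G>A
sg4_01	sgRNA4	WT	610C>G
sg4_02	sgRNA4	WT	605del
sg4_03	sgRNA4	WT	612–613del
sg4_04	sgRNA4	WT	618del
sg4_05	sgRNA4	WT	621del
sg4_06	sgRNA4	WT	622del
sg4_07	sgRNA4	WT	621–622del
sg4_08	sgRNA4	WT	150T>A
sg4_09	sgRNA4	WT	230T>A
sg4_10	sgRNA4	WT	340T>A
sg4_11	sgRNA4	WT	480A>C
sg4_12	sgRNA4	WT	520T>A
sg4_13	sgRNA4	WT	700C>A
sg4_14	sgRNA4	WT	750T>A
sg4_15	sgRNA4	WT	850T>A
sg4_16	sgRNA4	WT	1000C>A
sg4_17	sgRNA4	WT	1150C>A
sg4_18	sgRNA4	WT	1300T>A
sg4_19	sgRNA4	WT	1450T>A
sg4_20	sgRNA4	WT	1600C>A
sg6_01	sgRNA6	WT	950del
sg6_02	sgRNA6	WT	951del
sg6_03	sgRNA6	WT	948del
sg6_04	sgRNA6	WT	953del
sg6_05	sgRNA6	WT	950del
sg6_06	sgRNA6	WT	949ins(T)
sg6_07	sgRNA6	WT	952ins(T)
sg6_08	sgRNA6	WT	951ins(T)
sg6_09	sgRNA6	WT	948ins(T)
sg6_10	sgRNA6	WT	952del
sg6_11	sgRNA6	WT	943C>T
sg6_12	sgRNA6	WT	945C>T
sg6_13	sgRNA6	WT	956C>T
sg6_14	sgRNA6	WT	958C>T
sg6_15	sgRNA6	WT	942A>C, 946A>C
sg6_16	sgRNA6	WT	955T>A, 959A>C
sg6_17	sgRNA6	WT	943C>A, 945–946del
sg6_18	sgRNA6	WT	956C>G, 959–960del
sg6_19	sgRNA6	WT	944T>A, 947A>C
sg6_20	sgRNA6	WT	957T>A, 960A>C
sg6_21	sgRNA6	WT	200G>A
sg6_22	sgRNA6	WT	400G>A
sg6_23	sgRNA6	WT	600A>C
sg6_24	sgRNA6	WT	1100T>A
sg6_25	sgRNA6	WT	1400C>A
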