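isolate_id	guide_id	genotype	mutations
sg1_01	sgRNA1	WT	259G>T
sg1_02	sgRNA1	WT	263T>G
sg1_03	sgRNA1	WT	282T>A, 286–287del
sg1_04	sgRNA1	WT	286–287del
sg1_05	sgRNA1	WT	287T>A
sg1_06	sgRNA1	WT	287T>A, 289G>C
sg1_07	sgRNA1	WT	290C>A
sg1_08	sgRNA1	WT	290ins(22 bp)
sg1_09	sgRNA1	WT	291C>G, 294T>A
sg1_10	sgRNA1	WT	292del
sg1_11	sgRNA1	WT	294ins(T)
sg1_12	sgRNA1	WT	591C>A
sg1_13	sgRNA1	WT	801–808del
sg1_14	sgRNA1	WT	809G>A
sg1_15	sgRNA1	WT	892del
sg1_16	sgRNA1	WT	923G>T
sg1_17	sgRNA1	WT	973G>T
sg1_18	sgRNA1	WT	1035C>A
sg1_19	sgRNA1	WT	1068C>A
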