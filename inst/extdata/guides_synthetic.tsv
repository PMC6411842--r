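id	start	end	strand	pam_side
sgRNA1	277	296	TS	upstream
sgRNA2	291	310	NTS	downstream
sgRNA3	701	720	TS	upstream
sgRNA4	601	620	NTS	downstream
sgRNA5	1101	1120	TS	upstream
sgRNA6	941	960	NTS	downstream
sgRNA7	401	420	TS	upstream
sgRNA8	405	424	TS	upstream
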