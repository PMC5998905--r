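reaction_id	equation	lower_bound	upper_bound	gpr	subsystem
EX_A_in	=> A	0	10		
R1	A => B	0	1000	g1 and g2	glycolysis
R2	B <=> 2 C	-1000	1000	g3 or g4	tca
EX_C_out	C =>	0	1000		
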