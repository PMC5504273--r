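@HD	VN:1.6	SO:coordinate
@SQ	SN:G1	LN:5000
@SQ	SN:G2	LN:5000
r1	0	G1	100	60	50M	*	0	0	*	*
r2	0	G1	200	60	50M	*	0	0	*	*
amb1	0	G1	400	1	50M	*	0	0	*	*
amb1	256	G2	300	1	50M	*	0	0	*	*
r3	0	G2	350	60	50M	*	0	0	*	*
u1	4	*	0	0	*	*	0	0	*	*
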