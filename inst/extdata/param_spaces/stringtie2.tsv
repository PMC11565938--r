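name	kind	default	warmup_step
t	binary	0	1
u	binary	0	1
m	integer	200	40
a	integer	10	2
g	integer	50	10
j	float	1	0.2
f	float	0.01	0.1
M	float	1	0.2
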