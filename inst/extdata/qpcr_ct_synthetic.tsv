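gene	role	input_fraction	replicate	ct
TGT_A	bound	0.00027	1	26
TGT_A	bound	0.00027	2	26
TGT_A	bound	0.00027	3	26
TGT_A	negctrl	0.00027	1	33
TGT_A	negctrl	0.00027	2	33.2
TGT_A	negctrl	0.00027	3	32.8
TGT_A	input	0.00027	1	30
TGT_A	input	0.00027	2	30
TGT_A	input	0.00027	3	30
TGT_B	bound	0.00027	1	25.5
TGT_B	bound	0.00027	2	26
TGT_B	bound	0.00027	3	26.5
TGT_B	negctrl	0.00027	1	32.5
TGT_B	negctrl	0.00027	2	33
TGT_B	negctrl	0.00027	3	33.5
TGT_B	input	0.00027	1	30
TGT_B	input	0.00027	2	30
TGT_B	input	0.00027	3	30
TGT_C	bound	0.00027	1	24
TGT_C	bound	0.00027	2	24.5
TGT_C	bound	0.00027	3	25
TGT_C	negctrl	0.00027	1	32
TGT_C	negctrl	0.00027	2	32.5
TGT_C	negctrl	0.00027	3	33
TGT_C	input	0.00027	1	30
TGT_C	input	0.00027	2	30
TGT_C	input	0.00027	3	30
NEGREF	bound	0.00027	1	28
NEGREF	bound	0.00027	2	28
NEGREF	bound	0.00027	3	28
NEGREF	input	0.00027	1	30
NEGREF	input	0.00027	2	30
NEGREF	input	0.00027	3	30
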