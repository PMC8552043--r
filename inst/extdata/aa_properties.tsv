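aa	kd_hydropathy	grantham_polarity	aliphatic_coef	aromatic	acidic	basic	pka_side	charge_sign
A	1.8	8.1	1	0	0	0	NA	0
R	-4.5	10.5	0	0	0	1	12.48	1
N	-3.5	11.6	0	0	0	0	NA	0
D	-3.5	13.0	0	0	1	0	3.65	-1
C	2.5	5.5	0	0	0	0	8.3	-1
Q	-3.5	10.5	0	0	0	0	NA	0
E	-3.5	12.3	0	0	1	0	4.25	-1
G	-0.4	9.0	0	0	0	0	NA	0
H	-3.2	10.4	0	1	0	1	6.0	1
I	4.5	5.2	3.9	0	0	0	NA	0
L	3.8	4.9	3.9	0	0	0	NA	0
K	-3.9	11.3	0	0	0	1	10.53	1
M	1.9	5.7	0	0	0	0	NA	0
F	2.8	5.2	0	1	0	0	NA	0
P	-1.6	8.0	0	0	0	0	NA	0
S	-0.8	9.2	0	0	0	0	NA	0
T	-0.7	8.6	0	0	0	0	NA	0
W	-0.9	5.4	0	1	0	0	NA	0
Y	-1.3	6.2	0	1	0	0	10.07	-1
V	4.2	5.9	2.9	0	0	0	NA	0
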