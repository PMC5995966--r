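label	x	y	z
FP1	-22	70	0
FP2	24	70	0
F7	-55	34	-4
F3	-40	25	45
FZ	0	27	61
F4	39	26	47
F8	56	34	-4
T3	-70	-21	-11
C3	-52	-16	58
CZ	0	-15	74
C4	55	-18	59
T4	72	-25	-8
T5	-62	-65	1
P3	-40	-76	47
PZ	0	-62	65
P4	37	-75	49
T6	59	-68	4
O1	-27	-100	13
O2	24	-100	14
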