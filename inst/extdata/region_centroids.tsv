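region	x	y	z
Temporal	-58	-20	-10
Temporal	58	-20	-10
Parietal	0	-60	50
Parietal	-38	-68	45
Parietal	38	-68	45
Frontal	0	40	35
Frontal	-40	35	20
Frontal	40	35	20
Occipital	0	-90	5
Occipital	-25	-95	15
Occipital	25	-95	15
Sub-lobar	0	0	5
Limbic	0	-25	25
Cerebellar	0	-70	-35
Pituitary	0	5	-25
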