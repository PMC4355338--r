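isoform	I	II	III	IV	VA	VB	VI	VII	IX	XII	XIII	XIV
I	-	158	141	78	126	128	82	132	83	91	154	85
II	60.5	-	152	88	133	138	90	147	85	89	157	96
III	54.2	58.5	-	82	120	117	87	130	80	86	151	90
IV	30.0	33.5	31.2	-	89	93	97	90	84	91	84	62
VA	48.1	50.8	45.4	23.6	-	184	93	131	83	84	124	88
VB	46.9	51.9	43.5	23.1	58.7	-	82	134	89	79	131	88
VI	31.9	33.5	32.3	27.0	27.9	24.4	-	93	107	104	90	106
VII	50.8	56.2	49.6	31.8	48.5	49.2	34.9	-	95	103	139	97
IX	33.1	34.2	31.1	27.2	31.9	32.7	38.9	37.0	-	101	90	113
XII	35.8	34.2	32.3	28.1	31.6	29.7	38.0	38.0	38.9	-	91	123
XIII	59.2	59.6	57.7	28.2	46.2	47.7	33.2	52.7	35.0	34.7	-	98
XIV	34.2	35.8	34.2	29.0	31.9	29.0	35.8	36.0	44.4	46.0	37.4	-
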