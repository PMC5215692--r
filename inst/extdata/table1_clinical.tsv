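covariate	category	group	count
gender	female	all	294
gender	male	all	414
gender	female	L1	88
gender	male	L1	149
gender	female	L3	120
gender	male	L3	180
gender	female	L2	86
gender	male	L2	85
age_decades	le16	all	115
age_decades	17to40	all	442
age_decades	gt40	all	151
age_decades	le16	L1	29
age_decades	17to40	L1	150
age_decades	gt40	L1	58
age_decades	le16	L3	60
age_decades	17to40	L3	186
age_decades	gt40	L3	54
age_decades	le16	L2	26
age_decades	17to40	L2	106
age_decades	gt40	L2	39
smoking	yes	all	218
smoking	no	all	366
smoking	ex	all	108
smoking	missing	all	16
smoking	yes	L1	76
smoking	no	L1	114
smoking	ex	L1	38
smoking	missing	L1	9
smoking	yes	L3	95
smoking	no	L3	156
smoking	ex	L3	43
smoking	missing	L3	6
smoking	yes	L2	47
smoking	no	L2	96
smoking	ex	L2	27
smoking	missing	L2	1
behavior	B1	all	537
behavior	B2	all	102
behavior	B3	all	69
behavior	B1	L1	164
behavior	B2	L1	47
behavior	B3	L1	26
behavior	B1	L3	224
behavior	B2	L3	44
behavior	B3	L3	32
behavior	B1	L2	149
behavior	B2	L2	11
behavior	B3	L2	11
familial_cd	yes	all	66
familial_cd	no	all	627
familial_cd	missing	all	15
familial_cd	yes	L1	24
familial_cd	no	L1	208
familial_cd	missing	L1	5
familial_cd	yes	L3	29
familial_cd	no	L3	267
familial_cd	missing	L3	4
familial_cd	yes	L2	13
familial_cd	no	L2	152
familial_cd	missing	L2	6
surgical_presentation	yes	all	88
surgical_presentation	no	all	574
surgical_presentation	missing	all	46
surgical_presentation	yes	L1	41
surgical_presentation	no	L1	186
surgical_presentation	missing	L1	10
surgical_presentation	yes	L3	37
surgical_presentation	no	L3	238
surgical_presentation	missing	L3	25
surgical_presentation	yes	L2	10
surgical_presentation	no	L2	150
surgical_presentation	missing	L2	11
perianal	yes	all	15
perianal	no	all	683
perianal	missing	all	10
perianal	yes	L1	4
perianal	no	L1	229
perianal	missing	L1	4
perianal	yes	L3	8
perianal	no	L3	290
perianal	missing	L3	2
perianal	yes	L2	3
perianal	no	L2	164
perianal	missing	L2	4
upper_gi	yes	all	47
upper_gi	no	all	661
upper_gi	yes	L1	17
upper_gi	no	L1	220
upper_gi	yes	L3	25
upper_gi	no	L3	275
upper_gi	yes	L2	5
upper_gi	no	L2	166
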