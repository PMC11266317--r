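# Material registry for the phantom pipeline: ICRU-44-style tissue-equivalent
# compositions, a generic plastic-water surrogate (the manufacturer's exact
# composition is proprietary and not packaged), stoichiometric plastics for the
# quantification phantom, and hydroxyapatite bone inserts (HA mass concentration
# mixed into the plastic-water base). Drop-in replacement files with identical
# schema (e.g. manufacturer datasheet values) are supported by read_material_registry().
# columns: material  density_g_cm3  element  mass_fraction
material	density_g_cm3	element	mass_fraction
air	0.001205	N	0.755
air	0.001205	O	0.232
air	0.001205	Ar	0.013
water	1	H	0.1119
water	1	O	0.8881
plastic_water	1.045	H	0.081
plastic_water	1.045	C	0.672
plastic_water	1.045	N	0.024
plastic_water	1.045	O	0.199
plastic_water	1.045	Cl	0.001
plastic_water	1.045	Ca	0.023
lung_inhale	0.204	H	0.103
lung_inhale	0.204	C	0.105
lung_inhale	0.204	N	0.031
lung_inhale	0.204	O	0.749
lung_inhale	0.204	Na	0.002
lung_inhale	0.204	P	0.002
lung_inhale	0.204	S	0.003
lung_inhale	0.204	Cl	0.003
lung_inhale	0.204	K	0.002
lung_exhale	0.507	H	0.103
lung_exhale	0.507	C	0.105
lung_exhale	0.507	N	0.031
lung_exhale	0.507	O	0.749
lung_exhale	0.507	Na	0.002
lung_exhale	0.507	P	0.002
lung_exhale	0.507	S	0.003
lung_exhale	0.507	Cl	0.003
lung_exhale	0.507	K	0.002
adipose	0.96	H	0.114
adipose	0.96	C	0.598
adipose	0.96	N	0.007
adipose	0.96	O	0.278
adipose	0.96	Na	0.001
adipose	0.96	S	0.001
adipose	0.96	Cl	0.001
breast	0.99	H	0.106
breast	0.99	C	0.332
breast	0.99	N	0.03
breast	0.99	O	0.527
breast	0.99	Na	0.001
breast	0.99	P	0.001
breast	0.99	S	0.002
breast	0.99	Cl	0.001
muscle	1.06	H	0.102
muscle	1.06	C	0.143
muscle	1.06	N	0.034
muscle	1.06	O	0.71
muscle	1.06	Na	0.001
muscle	1.06	P	0.002
muscle	1.06	S	0.003
muscle	1.06	Cl	0.001
muscle	1.06	K	0.004
liver	1.07	H	0.102
liver	1.07	C	0.139
liver	1.07	N	0.03
liver	1.07	O	0.716
liver	1.07	Na	0.002
liver	1.07	P	0.003
liver	1.07	S	0.003
liver	1.07	Cl	0.002
liver	1.07	K	0.003
cortical_bone	1.92	H	0.034
cortical_bone	1.92	C	0.155
cortical_bone	1.92	N	0.042
cortical_bone	1.92	O	0.435
cortical_bone	1.92	Na	0.001
cortical_bone	1.92	Mg	0.002
cortical_bone	1.92	P	0.103
cortical_bone	1.92	S	0.003
cortical_bone	1.92	Ca	0.225
polystyrene	0.023	H	0.0774253
polystyrene	0.023	C	0.922575
ptfe	2.18	C	0.240186
ptfe	2.18	F	0.759814
polyamide	1.02	H	0.0979852
polyamide	1.02	C	0.63685
polyamide	1.02	N	0.12378
polyamide	1.02	O	0.141384
polypropylene	0.91	H	0.143723
polypropylene	0.91	C	0.856277
bone_ha200	1.16	Ca	0.0878171
bone_ha200	1.16	P	0.0318949
bone_ha200	1.16	O	0.23608
bone_ha200	1.16	H	0.0673805
bone_ha200	1.16	C	0.556138
bone_ha200	1.16	N	0.0198621
bone_ha200	1.16	Cl	0.000827586
bone_ha800	1.53	Ca	0.21957
bone_ha800	1.53	P	0.096727
bone_ha800	1.53	O	0.311452
bone_ha800	1.53	H	0.0396963
bone_ha800	1.53	C	0.320627
bone_ha800	1.53	N	0.011451
bone_ha800	1.53	Cl	0.000477124
bone_ha1250	1.82	Ca	0.2812
bone_ha1250	1.82	P	0.127054
bone_ha1250	1.82	O	0.346708
bone_ha1250	1.82	H	0.0267464
bone_ha1250	1.82	C	0.210462
bone_ha1250	1.82	N	0.00751648
bone_ha1250	1.82	Cl	0.000313187
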