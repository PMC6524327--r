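name	category	lower_bound	upper_bound	complement	conditional_rule
CADD	composite	-7.53	35.79	FALSE	none
DANN	composite	0	1	FALSE	none
FATHMM	functionality	-16.13	10.64	TRUE	none
fathmm-MKL	composite	0	1	FALSE	none
GERP++_RS	conservation	-12.3	6.17	FALSE	none
M-CAP	composite	0	1	FALSE	none
MetaLR	composite	0	1	FALSE	none
MetaSVM	composite	-2	3	FALSE	none
MutationTaster	functionality	0	1	FALSE	class_dependent
phastCons	conservation	0	1	FALSE	none
phyloP	conservation	-13.28	1.2	FALSE	none
Polyphen2_HDIV	functionality	0	1	FALSE	none
Polyphen2_HVAR	functionality	0	1	FALSE	none
PROVEAN	functionality	-14	14	TRUE	none
SIFT	functionality	0	1	TRUE	none
VEST3	functionality	0	1	FALSE	none
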