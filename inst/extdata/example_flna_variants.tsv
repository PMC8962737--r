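sample_id	patient_id	tumor_group	chrom	start	end	ref	alt	gene	variant_class	depth	exac_eas_freq	vest_indel_score	vest_indel_p	aa_change	SIFT	Polyphen2_HDIV	Polyphen2_HVAR	LRT	MutationTaster	MutationAssessor	FATHMM	PROVEAN	VEST3	MetaSVM	MetaLR	M_CAP	CADD	FATHMM_MKL	fitCons
Patient1-M	Patient1	metastatic	X	154360534	154360570	GCGGGCGGGGGAGCCCGCACTGCCTCCCTGCAGCCCC	-	FLNA	frameshift_indel	100	.	0.95	0.001	P1075fs	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Patient1-M	Patient1	metastatic	X	154362486	154362491	TGTCAT	-	FLNA	nonframeshift_indel	100	.	0.95	0.001	831_833del	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Patient2-M	Patient2	metastatic	X	154359888	154359891	TGGC	-	FLNA	frameshift_indel	100	.	0.95	0.001	A1274fs	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Patient6-M	Patient6	metastatic	X	154362486	154362491	TGTCAT	-	FLNA	nonframeshift_indel	100	.	0.95	0.001	831_833del	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Patient8-M	Patient8	metastatic	X	154362486	154362491	TGTCAT	-	FLNA	nonframeshift_indel	100	.	0.95	0.001	831_833del	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Patient1-P	Patient1	primary	X	154361680	154361687	GCCAGACA	-	FLNA	frameshift_indel	100	.	0.95	0.001	V976fs	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Patient2-P	Patient2	primary	X	154362486	154362491	TGTCAT	-	FLNA	nonframeshift_indel	100	.	0.95	0.001	831_833del	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
Patient4-P	Patient4	primary	X	154366374	154366374	C	T	FLNA	nonsynonymous_SNV	100	.	.	.	G388S	D	D	D	D	A	H	D	D	0.75	D	D	D	30	D	1.05
Patient7-P	Patient7	primary	X	154354220	154354220	C	T	FLNA	nonsynonymous_SNV	100	.	.	.	V1822M	D	D	D	D	A	H	D	D	0.75	D	D	D	30	D	1.05
Patient8-P	Patient8	primary	X	154352600	154352600	G	A	FLNA	nonsynonymous_SNV	100	.	.	.	S2144L	D	D	D	D	A	H	D	D	0.75	D	D	D	30	D	1.05
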