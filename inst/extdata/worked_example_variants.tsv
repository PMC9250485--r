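chrom	pos	ref	alt	gene	region_class	exonic_effect	qual	depth	fwd_reads	rev_reads	caller_filter	gt_III2	gt_III3	gt_III4	gt_III5	gt_IV2	gt_III1	af_1000g_eur	af_exac_nfe	af_esp6500	af_local	af_gnomad_nfe	cadd_phred	gerp	phastcons	phylop	intol_local	intol_esp6500	intol_exac	exac_z	exac_pli	pred_SIFT	pred_PP2_HumDiv	pred_PP2_HumVar	pred_LRT	pred_MutationTaster	pred_MutationAssessor	pred_FATHMM	pred_ReliabilityIndex	pred_VEST3	pred_PROVEAN	snap2_effect	snap2_accuracy
9	132501952	C	T	PTGES	exonic	missense	60	40	20	20	PASS	0/1	0/1	0/1	0/1	0/1	0/0	0	0.00021	0	0	8.43e-05	34	4.67	1	7.72	-0.5	-0.3	-0.8	-0.1	.	D	D	P	D	D	M	T	4	0.7	D	16	59
12	129285482	T	C	SLC15A4	exonic	missense	60	40	20	20	PASS	0/1	0/1	0/1	0/1	0/1	0/0	0	0	0	0	0	23.7	5.49	0.91	5.6	-1.2	-0.9	-1.5	0.8	.	D	D	D	D	D	M	T	7	0.9	D	44	71
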