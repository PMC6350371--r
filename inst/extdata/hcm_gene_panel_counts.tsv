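gene	variant_class	case_carriers	n_cases	ref_carriers	ref_n
MYH7	non_truncating	849	6112	672	60469
MYBPC3	non_truncating	578	6179	555	45794
TNNT2	non_truncating	103	6103	86	57018
TNNI3	non_truncating	127	6047	79	52607
TPM1	non_truncating	64	4447	42	58642
MYL2	non_truncating	43	4185	69	60521
MYL3	non_truncating	35	4185	85	60605
ACTC1	non_truncating	22	4185	37	60198
PLN	non_truncating	9	5440	15	60475
CSRP3	non_truncating	30	4866	115	60647
FHL1	non_truncating	16	2061	53	60278
TNNC1	non_truncating	8	3335	33	59192
FLNC	non_truncating	17	448	1225	56897
FHOD3	non_truncating	72	3189	683	57035
MYBPC3	truncating	566	6179	40	45794
TNNT2	truncating	11	6103	17	57018
TNNI3	truncating	5	6047	5	52607
PLN	truncating	9	5440	4	60475
CSRP3	truncating	7	4866	14	60647
FHL1	truncating	3	2061	0	60278
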