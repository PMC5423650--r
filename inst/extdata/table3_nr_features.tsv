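gene	ftype	strand	start	end	anticodon	start_codon	stop_codon
tRNA-Ile	tRNA	J	1	67	GAT
tRNA-Gln	tRNA	N	65	133	TTG
tRNA-Met	tRNA	J	141	207	CAT
ND2	CDS	J	208	1233		ATG	TAA
tRNA-Trp	tRNA	J	1233	1303	TCA
tRNA-Cys	tRNA	N	1296	1365	GCA
tRNA-Tyr	tRNA	N	1384	1453	GTA
COX1	CDS	J	1458	2996		TTG	TAA
tRNA-Leu(UUR)	tRNA	J	3004	3067	TAA
COX2	CDS	J	3069	3753		ATG	T-
tRNA-Lys	tRNA	J	3754	3824	CTT
tRNA-Asp	tRNA	J	3825	3888	GTC
ATP8	CDS	J	3889	4047		ATT	TAA
ATP6	CDS	J	4041	4721		ATG	TAA
COX3	CDS	J	4721	5509		ATG	TAA
tRNA-Gly	tRNA	J	5514	5578	TCC
ND3	CDS	J	5579	5932		ATT	TAG
tRNA-Ala	tRNA	J	5931	5994	TGC
tRNA-Arg	tRNA	J	5994	6060	TCG
tRNA-Asn	tRNA	J	6065	6130	GTT
tRNA-Ser(AGN)	tRNA	J	6131	6198	GCT
tRNA-Glu	tRNA	J	6200	6263	TTC
tRNA-Phe	tRNA	N	6264	6329	GAA
ND5	CDS	N	6331	8058		ATA	TAA
tRNA-His	tRNA	N	8062	8127	GTG
ND4	CDS	N	8134	9471		ATG	TAA
ND4L	CDS	N	9465	9749		ATG	TAA
tRNA-Thr	tRNA	J	9753	9816	TGT
tRNA-Pro	tRNA	N	9817	9881	TGG
ND6	CDS	J	9884	10386		ATT	TA-
CYTB	CDS	J	10388	11519		ATG	T-
tRNA-Ser(UCN)	tRNA	J	11521	11591	TGA
ND1	CDS	N	11609	12556		ATG	TAA
tRNA-Leu(CUN)	tRNA	N	12560	12625	TAG
rrnL	rRNA	N	12626	13921
tRNA-Val	tRNA	N	13922	13993	TAC
rrnS	rRNA	N	13994	14808
CR	control_region	J	14809	15711
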