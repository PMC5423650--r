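gene	ftype	strand	start	end	anticodon	start_codon	stop_codon
tRNA-Ile	tRNA	J	1	67	GAT
tRNA-Gln	tRNA	N	65	133	TTG
tRNA-Met	tRNA	J	141	207	CAT
ND2	CDS	J	208	1236		ATG	TAA
tRNA-Trp	tRNA	J	1236	1306	TCA
tRNA-Cys	tRNA	N	1299	1366	GCA
tRNA-Tyr	tRNA	N	1376	1444	GTA
COX1	CDS	J	1449	2984		TTG	TAA
tRNA-Leu(UUR)	tRNA	J	2990	3055	TAA
COX2	CDS	J	3072	3756		ATG	T-
tRNA-Lys	tRNA	J	3757	3827	CTT
tRNA-Asp	tRNA	J	3828	3892	GTC
ATP8	CDS	J	3893	4051		ATT	TAA
ATP6	CDS	J	4045	4724		ATG	TA-
COX3	CDS	J	4725	5513		ATG	TAA
tRNA-Gly	tRNA	J	5518	5582	TCC
ND3	CDS	J	5583	5934		ATT	T-
tRNA-Ala	tRNA	J	5935	6000	TGC
tRNA-Arg	tRNA	J	6000	6066	TCG
tRNA-Asn	tRNA	J	6066	6131	GTT
tRNA-Ser(AGN)	tRNA	J	6132	6198	GCT
tRNA-Glu	tRNA	J	6200	6269	TTC
tRNA-Phe	tRNA	N	6271	6337	GAA
ND5	CDS	N	6338	8068		ATG	TAA
tRNA-His	tRNA	N	8069	8134	GTG
ND4	CDS	N	8137	9474		ATG	TAA
ND4L	CDS	N	9468	9752		ATG	TAA
tRNA-Thr	tRNA	J	9755	9818	TGT
tRNA-Pro	tRNA	N	9819	9885	TGG
ND6	CDS	J	9888	10387		ATT	TA-
CYTB	CDS	J	10388	11519		ATG	T-
tRNA-Ser(UCN)	tRNA	J	11525	11595	TGA
ND1	CDS	N	11621	12568		ATG	TAA
tRNA-Leu(CUN)	tRNA	N	12572	12635	TAG
rrnL	rRNA	N	12636	13943
tRNA-Val	tRNA	N	13944	14014	TAC
rrnS	rRNA	N	14015	14826
CR	control_region	J	14827	15605
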