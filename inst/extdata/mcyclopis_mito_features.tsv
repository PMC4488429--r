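# M. cyclopis mitogenome (KM023192) organization table, 1-based inclusive
# coordinates, genome length 16563 bp, circular.  printed_length and
# printed_spacer are the published Length and Intergenic spacer columns
# (spacer of the final feature, across the origin through the control
# region, is reported separately and left NA here).
name	start	end	strand	ftype	printed_length	printed_spacer
tRNA-Phe	538	609	H	tRNA	72	0
rrnS	610	1556	H	rRNA	947	0
tRNA-Val	1557	1625	H	tRNA	69	0
rrnL	1626	3184	H	rRNA	1559	0
tRNA-Leu(L2)	3185	3259	H	tRNA	75	2
ND1	3262	4216	H	PCG	955	0
tRNA-Ile	4217	4285	H	tRNA	69	-3
tRNA-Gln	4283	4354	L	tRNA	72	1
tRNA-Met	4356	4423	H	tRNA	68	0
ND2	4424	5465	H	PCG	1042	0
tRNA-Trp	5466	5532	H	tRNA	67	7
tRNA-Ala	5540	5608	L	tRNA	69	1
tRNA-Asn	5610	5682	L	tRNA	73	32
tRNA-Cys	5715	5783	L	tRNA	69	0
tRNA-Tyr	5784	5847	L	tRNA	64	4
COX1	5852	7420	H	PCG	1569	-28
tRNA-Ser(S2)	7393	7461	L	tRNA	69	3
tRNA-Asp	7465	7532	H	tRNA	68	1
COX2	7534	8217	H	PCG	684	73
tRNA-Lys	8291	8353	H	tRNA	63	1
ATP8	8355	8561	H	PCG	207	-46
ATP6	8516	9196	H	PCG	681	-1
COX3	9196	9979	H	PCG	784	0
tRNA-Gly	9980	10047	H	tRNA	68	0
ND3	10048	10393	H	PCG	346	0
tRNA-Arg	10394	10458	H	tRNA	65	0
ND4L	10459	10755	H	PCG	297	-7
ND4	10749	12126	H	PCG	1378	0
tRNA-His	12127	12195	H	tRNA	69	0
tRNA-Ser(S1)	12196	12254	H	tRNA	59	0
tRNA-Leu(L1)	12255	12325	H	tRNA	71	0
ND5	12326	14137	H	PCG	1812	0
ND6	14138	14665	L	PCG	528	0
tRNA-Glu	14666	14734	L	tRNA	69	4
CYTB	14739	15879	H	PCG	1141	0
tRNA-Thr	15880	15943	H	tRNA	64	1
tRNA-Pro	15945	16012	L	tRNA	68	NA
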