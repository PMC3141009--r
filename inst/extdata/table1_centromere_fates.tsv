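ancestral_label	species	track	token	status	chrom	scer_strand	orientation_change	possible_orientation	translocation_at_cen	inversion_at_cen
Anc_CEN1	S.cerevisiae	1	3+	mapped	3	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN1	S.cerevisiae	2	14+	mapped	14	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN1	S.bayanus	1	3	mapped	3	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN1	S.bayanus	2	14	mapped	14	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN1	C.glabrata	1	2r	mapped	2	NA	FALSE	FALSE	TRUE	FALSE
Anc_CEN1	C.glabrata	2	X	lost	NA	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN1	V.polyspora	1	s1050	mapped	s1050	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN1	V.polyspora	2	Xr	lost	NA	NA	FALSE	FALSE	TRUE	FALSE
Anc_CEN1	Z.rouxii	1	5	mapped	5	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN1	K.lactis	1	1r	mapped	1	NA	FALSE	FALSE	TRUE	FALSE
Anc_CEN1	A.gossypii	1	1	mapped	1	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN1	L.kluyveri	1	4*	mapped	4	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN1	L.thermotolerans	1	8	mapped	8	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN1	L.waltii	1	s0	mapped	s0	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	S.cerevisiae	1	8-	mapped	8	-	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	S.cerevisiae	2	11-	mapped	11	-	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	S.bayanus	1	8	mapped	8	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	S.bayanus	2	11	mapped	11	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	C.glabrata	1	11i	mapped	11	NA	FALSE	FALSE	FALSE	TRUE
Anc_CEN2	C.glabrata	2	X	lost	NA	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	V.polyspora	1	s1056*	mapped	s1056	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN2	V.polyspora	2	s1018	mapped	s1018	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	Z.rouxii	1	X	lost	NA	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	K.lactis	1	2	mapped	2	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	A.gossypii	1	2	mapped	2	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN2	L.kluyveri	1	1*	mapped	1	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN2	L.thermotolerans	1	4*	mapped	4	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN2	L.waltii	1	s26*	mapped	s26	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN3	S.cerevisiae	1	2+	mapped	2	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	S.cerevisiae	2	4+	mapped	4	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	S.bayanus	1	2	mapped	2	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	S.bayanus	2	4	mapped	4	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	C.glabrata	1	3*	mapped	3	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN3	C.glabrata	2	13	mapped	13	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	V.polyspora	1	s1036	mapped	s1036	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	V.polyspora	2	s1045	mapped	s1045	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	Z.rouxii	1	1	mapped	1	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	K.lactis	1	X	lost	NA	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	A.gossypii	1	5	mapped	5	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	L.kluyveri	1	3	mapped	3	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN3	L.thermotolerans	1	7*	mapped	7	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN3	L.waltii	1	s27*	mapped	s27	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN4	S.cerevisiae	1	1+	mapped	1	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN4	S.cerevisiae	2	7-	mapped	7	-	FALSE	FALSE	FALSE	FALSE
Anc_CEN4	S.bayanus	1	1	mapped	1	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN4	S.bayanus	2	7	mapped	7	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN4	C.glabrata	1	1i	mapped	1	NA	FALSE	FALSE	FALSE	TRUE
Anc_CEN4	C.glabrata	2	7r	mapped	7	NA	FALSE	FALSE	TRUE	FALSE
Anc_CEN4	V.polyspora	1	s1062	mapped	s1062	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN4	V.polyspora	2	X	lost	NA	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN4	Z.rouxii	1	7	mapped	7	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN4	K.lactis	1	3*	mapped	3	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN4	A.gossypii	1	6	mapped	6	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN4	L.kluyveri	1	8*	mapped	8	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN4	L.thermotolerans	1	5*	mapped	5	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN4	L.waltii	1	s47*	mapped	s47	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN5	S.cerevisiae	1	10-	mapped	10	-	FALSE	FALSE	FALSE	FALSE
Anc_CEN5	S.cerevisiae	2	12-	mapped	12	-	FALSE	FALSE	FALSE	FALSE
Anc_CEN5	S.bayanus	1	10	mapped	10	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN5	S.bayanus	2	12	mapped	12	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN5	C.glabrata	1	4	mapped	4	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN5	C.glabrata	2	X	lost	NA	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN5	V.polyspora	1	s534	mapped	s534	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN5	V.polyspora	2	s2002	mapped	s2002	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN5	Z.rouxii	1	2	mapped	2	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN5	K.lactis	1	6r	mapped	6	NA	FALSE	FALSE	TRUE	FALSE
Anc_CEN5	A.gossypii	1	Xr	lost	NA	NA	FALSE	FALSE	TRUE	FALSE
Anc_CEN5	L.kluyveri	1	7*	mapped	7	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN5	L.thermotolerans	1	2*	mapped	2	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN5	L.waltii	1	s33*	mapped	s33	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN6	S.cerevisiae	1	13+	mapped	13	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	S.cerevisiae	2	15-	mapped	15	-	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	S.bayanus	1	13	mapped	13	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	S.bayanus	2	15	mapped	15	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	C.glabrata	1	5	mapped	5	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	C.glabrata	2	9?r	mapped	9	NA	FALSE	TRUE	TRUE	FALSE
Anc_CEN6	V.polyspora	1	s1032	mapped	s1032	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	V.polyspora	2	s1037	mapped	s1037	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	Z.rouxii	1	3	mapped	3	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	K.lactis	1	X	lost	NA	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	A.gossypii	1	3	mapped	3	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	L.kluyveri	1	5	mapped	5	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	L.thermotolerans	1	3	mapped	3	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN6	L.waltii	1	s56	mapped	s56	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	S.cerevisiae	1	5+	mapped	5	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	S.cerevisiae	2	9+	mapped	9	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	S.bayanus	1	5	mapped	5	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	S.bayanus	2	9	mapped	9	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	C.glabrata	1	8r	mapped	8	NA	FALSE	FALSE	TRUE	FALSE
Anc_CEN7	C.glabrata	2	10	mapped	10	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	V.polyspora	1	s499	mapped	s499	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	V.polyspora	2	s312	mapped	s312	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	Z.rouxii	1	4	mapped	4	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	K.lactis	1	4*	mapped	4	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN7	A.gossypii	1	4	mapped	4	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	L.kluyveri	1	6	mapped	6	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	L.thermotolerans	1	6	mapped	6	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN7	L.waltii	1	s55	mapped	s55	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	S.cerevisiae	1	6+	mapped	6	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	S.cerevisiae	2	16+	mapped	16	+	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	S.bayanus	1	6	mapped	6	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	S.bayanus	2	16	mapped	16	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	C.glabrata	1	6	mapped	6	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	C.glabrata	2	12	mapped	12	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	V.polyspora	1	s354	mapped	s354	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	V.polyspora	2	s1058	mapped	s1058	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	Z.rouxii	1	6	mapped	6	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	K.lactis	1	5*	mapped	5	NA	TRUE	FALSE	FALSE	FALSE
Anc_CEN8	A.gossypii	1	7	mapped	7	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	L.kluyveri	1	2	mapped	2	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	L.thermotolerans	1	1	mapped	1	NA	FALSE	FALSE	FALSE	FALSE
Anc_CEN8	L.waltii	1	s23	mapped	s23	NA	FALSE	FALSE	FALSE	FALSE
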