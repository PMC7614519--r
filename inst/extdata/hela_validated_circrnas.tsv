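bsj_key	gene	variants	circatlas_id
chr21|45128401|45134832|+	ADARB1	290(2), 292(2), 293(2), 294(2), 296(2), 382(3), 506(4)	hsa-ADARB1_0010
chr8|61680967|61684188|-	ASPH	219(2), 264(3), 266(3), 333(4)	hsa-AC090094_0001
chr20|32366383|32369123|+	ASXL1	149(2), 192(2), 193(2), 195(3), 282(3)	hsa-ASXL1_0001
chr12|111552279|111555919|-	ATXN2	248(3), 320(4)	hsa-ATXN2_0002
chr16|88027482|88038011|+	BANP	407(4), 416(4)	hsa-BANP_0012
chr9|135881632|135883078|-	CAMSAP1	1024(2), 1033(2), 1446(1), 423(2), 425(2), 426(2), 587(3), 639(3)	hsa-CAMSAP1_0001
chr12|108652271|108654410|-	CORO1C	251(2), 274(3), 286(2), 395(3)	hsa-CORO1C_0003
chr7|156826604|156836885|-	LMBR1	253(3), 257(3), 267(3), 286(3), 331(3), 351(4), 371(4)	hsa-LMBR1_0004
chr8|140864311|140890769|-	PTK2	315(2), 482(3)	hsa-PTK2_0007
chr5|168488601|168494650|+	RARS	425(3), 478(4), 534(4)	hsa-RARS_0012
chr5|139278326|139279129|+	SNHG4	161(2), 249(2), 337(3), 493(2), 803(1)	hsa-SNHG4_0001
chr20|62854015|62860308|-	TCFL5	730(4), 733(4)	has-TCFL5_0001
chr3|142736378|142748460|+	TRPC1	358(2), 460(3)	hsa-TRPC1_0001
chr7|100023418|100024307|+	ZKSCAN1	578(3), 668(2)	hsa-ZKSCAN1_0001
chr3|125313307|125331238|-	ZNF148	487(3), 566(3), 604(4), 683(4)	hsa-ZNF148_0013
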