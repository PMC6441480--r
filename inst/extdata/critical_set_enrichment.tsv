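row	source	term_name	percent_gt	gt	genes
1	KEGG	HIF-1 signaling pathway	3.00	3	AKT1,GAPDH,APK3
2	KEGG	ErbB signaling pathway	3.49	3	AKT1,MAPK3,SRC
3	KEGG	VEGF signaling pathway	5.08	3	AKT1,MAPK3,SRC
4	KEGG	Estrogen signaling pathway	3.06	3	AKT1,MAPK3,SRC
5	KEGG	Prolactin signaling pathway	4.29	3	AKT1,MAPK3,SRC
6	KEGG	Thyroid hormone signaling pathway	3.45	4	AKT1,MAPK3,SRC,TP53
7	KEGG	Colorectal cancer	4.17	3	AKT1,MAPK3,TP53
8	KEGG	Pancreatic cancer	4.00	3	AKT1,MAPK3,TP53
9	KEGG	Endometrial cancer	5.17	3	AKT1,MAPK3,TP53
10	KEGG	Glioma	4.23	3	AKT1,MAPK3,TP53
11	KEGG	Prostate cancer	3.09	3	AKT1,MAPK3,TP53
12	KEGG	Melanoma	3.95	3	AKT1,MAPK3,TP53
13	KEGG	Bladder cancer	7.32	3	MAPK3,SRC,TP53
14	KEGG	Chronic myeloid leukemia	3.85	3	AKT1,MAPK3,TP53
15	KEGG	Non-small cell lung cancer	4.55	3	AKT1,MAPK3,TP53
16	KEGG	Central carbon metabolism in cancer	4.62	3	AKT1,MAPK3,TP53
17	REACTOME	PI5P, PP2A and IER3 Regulate PI3K/AKT Signaling	3.19	3	AKT1,MAPK3,SRC
18	WikiPathways	RANKL/RANK (Receptor activator of NFKB (ligand)) Signaling Pathway	5.45	3	AKT1,MAPK3,SRC
19	WikiPathways	Human Thyroid Stimulating Hormone (TSH) signaling pathway	4.55	3	AKT1,MAPK3,SRC
20	WikiPathways	Leptin signaling pathway	3.95	3	AKT1,MAPK3,SRC
21	WikiPathways	Follicle Stimulating Hormone (18) signaling pathway	11.11	3	AKT1,MAPK3,SRC
22	WikiPathways	Prolactin Signaling Pathway	3.95	3	AKT1,MAPK3,SRC
23	WikiPathways	Signaling Pathways in Glioblastoma	4.82	4	AKT1,MAPK3,SRC,TP53
24	WikiPathways	AGE/RAGE pathway	4.55	3	AKT1,MAPK3,SRC
25	WikiPathways	Interleukin-11 Signaling Pathway	6.82	3	AKT1,MAPK3,SRC
26	WikiPathways	Oncostatin M Signaling Pathway	6.15	4	AKT1,MAPK3,SRC,TP53
27	WikiPathways	Alpha 6 Beta 4 signaling pathway	9.09	3	AKT1,MAPK3,SRC
28	WikiPathways	IL-3 Signaling Pathway	6.12	3	AKT1,MAPK3,SRC
29	WikiPathways	Kit receptor signaling pathway	5.08	3	AKT1,MAPK3,SRC
30	WikiPathways	Rac1/Pak1/p38/MMP-2 pathway	5.97	4	AKT1,MAPK3,SRC,TP53
31	WikiPathways	Hepatitis C and Hepatocellular Carcinoma	5.88	3	AKT1,MAPK3,TP53
32	WikiPathways	Endometrial cancer	5.17	3	AKT1,MAPK3,TP53
33	WikiPathways	EPO Receptor Signaling	11.54	3	AKT1,MAPK3,SRC
34	GO_BiologicalProcess	regulation of telomerase activity	5.88	3	MAPK3,SRC,TP53
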