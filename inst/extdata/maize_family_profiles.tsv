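# Expression-context profile of maize (B73) cell-wall gene family subgroups
# from stem rind RNA-seq of internodes 4, 5, 6 and 8.
# n_total: annotated genes; n_expressed: >=95 reads per 20 M summed over the
# four internodes; class columns: counts among ratio-evaluable genes
# (>=500 reads per 20 M), classified by the (i4+i5)/(i6+i8) expression ratio.
family	n_total	n_expressed	n_elongation	n_transitional	n_secondary
Sucrose synthases	8	8	4	3	1
Nucleotide sugar interconversion	46	39	12	8	12
Nucleotide sugar transporters	65	58	20	15	15
Cellulose synthases (CesA)	20	19	6	5	6
GT8A (GUX)	7	6	2	2	0
GT8C (GATL)	10	7	3	2	1
GT43	16	14	0	6	6
GT47E	11	10	4	1	4
GT61	33	22	7	3	6
CslC	8	6	6	0	0
GT34 (XXT)	18	6	3	0	0
GT37 (FUT)	17	4	1	0	1
GT47A	23	5	3	1	0
CslA	10	10	8	1	0
GT106B (MSR)	6	6	6	0	0
CslF	9	7	4	0	1
AGP/Fasciclin	10	7	3	0	2
GT31	40	34	18	6	3
GT77	23	12	4	1	1
ER/Golgi resident	41	37	27	4	1
GT8D (GAUT)	23	23	16	3	2
GT106A (RRT), GT106C (PAGR), and D	16	13	6	3	1
GT47B	9	8	6	2	0
Polygalacturonases	47	19	8	3	1
Acetyl-transferases (TBL/BAHD)	77	59	20	13	6
GPI-anchored proteins (COB/SKU)	22	15	9	1	1
Expansins/XTHs	87	41	23	4	4
Monolignol synthesis	100	71	17	7	30
Peroxidases/Laccases	148	67	26	7	15
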