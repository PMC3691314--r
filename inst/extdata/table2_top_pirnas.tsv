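rank	id	pirna_sequence	pirna_counts	tag_sequence	tag_counts
1	DQ571592.1	AUCGGAACCUGCAGACACUCGUGGAGGCGUC	106965	UCGGAACCUGCAGACACUCGUGGAGGCGUC	77387
2	DQ601822.1	UAGGUGUGGAGCUUCCCGACCGGCUG	87638	UAGGUGUGGAGCUUCCCGACCGGCU	68013
3	DQ572237.1	UAUGAGCUUUAGAAUCAGUCAAGAGG	84463	UAUGAGCUUUAGAAUCAGUCAAGAGG	83929
4	DQ576939.1	UCGGAACCUGCAGACACUUGUGGAGGA	22571	UCGGAACCUGCAGACACUUGUGGAGGA	22190
5	DQ588372.1	UGGGAACGAGAAGACACUCAUGGAGG	22435	UGGGAACGAGAAGACACUCAUGG	8034
6	DQ588346.1	UGGGAACCAGAAGACACUCCUGGAGGAGUC	21052	UGGGAACCAGAAGACACUCCUGGAGGAGUC	20043
7	DQ601651.1	UAGGGACAAGAAGACACUCCUGCAGGAGUCGU	18391	UAGGGACAAGAAGACACUCCUGCAGGAGUC	17859
8	DQ569941.1	AAAGAAUGAAGAAGAACUUACUUGGCCU	16135	AAGAAUGAAGAAGAACUUACUUGGCCU	6886
9	DQ588403.1	UGGGAACGAGAAGACACUCGUGGAGGC	11005	UGGGAACGAGAAGACACUCGUGGAGGC	11004
10	DQ577923.1	UCUGCCUGAACUACACUGAGAAUGCAU	10495	UCUGCCUGAACUACACUGAGAAUGCAU	10436
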