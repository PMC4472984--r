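gene_id	role	forward_primer	reverse_primer
IF4a	reference	TGGACCAGAACACTAGGGACATT	AAACACGGGAAGACCCAGAA
CaNAC02	target	CCATGGGAGCTACCAAAGAA	TTTCGATCTCTCGGGCTAAA
CaNAC04	target	AACAAGACCACCTGACCCTG	AATGCGTCGATTTCTCAACC
CaNAC05	target	CTAAGGCAACGTTCGGAGAG	TTTGGCCTAGCACCATTAGG
CaNAC06	target	GTCCCTTCTGTGTCCACGAT	GCTCCACCACTCTGAACCTC
CaNAC16	target	CACCAAAGGGCCTCAAGACAG	GCCTCATGGATCCAATTTGCCTAT
CaNAC19	target	AGAGGTTTGGTTTGTTGGTG	CCAAACACATGGTGAGGAAA
CaNAC21	target	CTTACCCTTTACCCGCTTCC	TCTTCTCCCAAATCACCTGG
CaNAC24	target	TGCCACCAGGTTTTAGGTTC	AATGATGGAAACAGGCAAGG
CaNAC27	target	GCTTTGTTTGGGGATGAAGA	ACCTGCACCAGCTGCTCTAT
CaNAC40	target	ACGATCCTTGGGATCTTCCT	ATATTTCCTGTCTCGTGGCG
CaNAC41	target	CCTGAAGAGGCAATTGACAGA	TCACCACTGCAGTCAAAGGT
CaNAC43	target	CACTGGTGTTCTACGCTGGA	GCCGGCTGATCTATCAACAT
CaNAC44	target	CCCACATGGTACTCGTACTGG	TTGCAAGCCAGAAGAAGGAT
CaNAC46	target	TATTGGAAGGCAACAGGGTC	TTTCTTAGGCCAACAATGCC
CaNAC47	target	TTTCACACGGATTCAAGCTG	ACAAATTCGTTCCACTTGGG
CaNAC50	target	CCCACCGATGAAGAACTTGT	TACTGGAAGGGGTGCAGAAG
CaNAC52	target	GCTACATCAAAGCCATGCCC	GGCCTCACTCCATTTGGGTA
CaNAC57	target	GTGGTATGCAGGACCAAGCA	GGTGGTGGACGATGGTGATT
CaNAC67	target	ACAGGAGGAGAAGCTCGGAT	TCCTCATCCCGCTTTGAACC
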