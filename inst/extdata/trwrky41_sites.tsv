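gene_id	sequence	reverse_complement	iptm
AT5G04550	ACGAACTTGACTCGCTC	GAGCGAGTCAAGTTCGT	0.86
AT1G35435	TATGAAGCTTGACTAAC	GTTAGTCAAGCTTCATA	0.85
AT2G04630	CTGAACTTGACTCGAAA	TTTCGAGTCAAGTTCAG	0.85
AT1G09570	TCATATTTGTTTTGTTC	GAACAAAACAAATATGA	0.84
AT1G20450	TCCAATCTGTTTCTTCT	AGAAGAAACAGATTGGA	0.84
AT1G67320	TAGTGATAGTCAACTTG	CAAGTTGACTATCACTA	0.83
AT1G20800	GAAGACGAGTCAAGTAG	CTACTTGACTCGTCTTC	0.83
AT1G20440	GAGTGACCACCCCAATG	CATTGGGGTGGTCACTC	0.86
AT1G21240	CACAGCTTGACTCATAT	ATATGAGTCAAGCTGTG	0.83
AT1G20810	TCTACTTGACTCGTCTT	AAGACGAGTCAAGTAGA	0.82
AT1G44170	AATTATTTGTTTTGTTA	TAACAAAACAAATAATT	0.82
AT2G40910	CCTGCAGTTACGATGAT	ATCATCGTAACTGCAGG	0.82
AT2G39350	AGATAACTTGACTCGAA	TTCGAGTCAAGTTATCT	0.82
AT2G47790	AAAAGTTGACTATCATT	AATGATAGTCAACTTTT	0.82
AT5G57530	ATGATTGACTGAGATTT	AAATCTCAGTCAATCAT	0.82
AT5G47910	AAAGGATTTTGACCAGA	TCTGGTCAAAATCCTTT	0.82
AT1G32750	GATATTTGTTTTGTTTG	CAAACAAAACAAATATC	0.81
AT1G63500	ATAACTAGTTATATGAA	TTCATATAACTAGTTAT	0.81
AT2G42540	TCTATACCACTGTAAAA	TTTTACAGTGGTATAGA	0.81
AT1G47480	ATCAAAGCTTGACTCTC	GAGAGTCAAGCTTTGAT	0.81
AT5G17970	TAAAAGCTTGACTCAGC	GCTGAGTCAAGCTTTTA	0.81
AT5G44580	AACAGCTTGACTCAGAC	GTCTGAGTCAAGCTGTT	0.80
AT2G44140	CGTAACTTGACTCGATA	TATCGAGTCAAGTTACG	0.80
AT5G35580	CTAGAAGCTTGACTCGC	GCGAGTCAAGCTTCTAG	0.80
AT5G13320	AAAACATTGACCCAGAC	GTCTGGGTCAATGTTTT	0.80
AT5G57540	TATGATTGACTGAGATT	AATCTCAGTCAATCATA	0.80
AT2G36270	TCACAAAACAAATCATG	CATGATTTGTTTTGTGA	0.80
AT5G15970	TCAACAAATATACAACT	AGTTGTATATTTGTTGA	0.80
AT1G43890	AGGTTGGATTTTGATCG	CGATCAAAATCCAACCT	0.80
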