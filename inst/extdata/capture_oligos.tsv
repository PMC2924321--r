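start_position	sequence	set_label
32557347	GAGTGCGTTTGGTTTCTGACGAAGA	first
32565483	ACACAGCATGGAGCCAGATAGACAA	first
32573772	TCCGCTGGTTTCCTCTTGTATGTCT	first
32581764	TGCAGAAACTCCTCCAACTCACCAT	first
32589761	CGTCACTCATGTTTGTGGATGTGCT	first
32598047	GGCTGATAACTCTGCACTGAGACCT	first
32605292	GGGAAAATGATCCACAGGTCCAGGT	first
32613439	AGACACAGCGCCTTTATTACCTCCA	first
32622385	TACATCACACACTGGCATCTGGGT	first
32629186	CGGGAAAAGAGGATTTACCCAGGGA	first
32637220	AGCCCGTTCTTCTAGGTTCTTGAGG	first
32645745	GAGGACATCTGAAATGCTTGGAGCC	first
32654005	TGAGTTTGTAAGTGAGCTGTGCTGC	first
32661561	AGCACTCTTCTTGCAGTGGCTCTAT	first
32669516	TTACCTGATGTGCGACAAGTGATGG	first
32677260	GGTTCTCCAGGCATCTAATCTCGCT	first
32685963	GTTCTGGTGTTAAGGATCTGCGAGC	first
32693461	GCAGCAAGTCCTCTAATCTGCCAAG	first
32702671	ATGCAACGGAGGTGAGGTTTGTGA	first
32709282	ATCGTACATGAGCTGCAATGCCTTC	first
32718576	GTCGCTGAGATGCAACGTGTACTT	first
32726077	TGATTTGCTCAACCCCTTGCTCAAC	first
32733197	GATGAACCACGACTGTCATGCCCTT	first
32741331	TTTGACTTTGCCAGGAACACCAGC	first
32749953	ATCCCAACGATGTGCACCTGAAAAG	first
32757988	AACTGCTTGTCACATGCTCCACATC	first
32766047	CAAACTGACAAGGTTGCCCTGATGT	first
32774043	ACTAGCCCAGACCTGTGTGATCCTA	first
32781606	TTTGTCAAATCCAGCCACCTGACAC	first
32789661	GGACCTGGCGGGCATTAAACAATAG	first
32797206	TCGTCAGATAGGACTGAAAACGCCA	first
32805201	CCCTCCAGACACTCGAAGTTGTCATA	first
32813828	TTTGCTTTGGGGAGGATTGCATCAG	first
32821258	TGACTCCCTCCTTCGTATTGACAGC	first
32829736	GCAGGACAGGATGAGTGATGTGAAC	first
32837643	CTGTGACCCGCTGCTAATGTTTCAA	first
32845311	GAGCCACCCCTGTTTAAGCATTCAT	first
32853241	CACACAGTTGCCAGATTGCTTCGTA	first
32861615	ATTATGCCTGCATGTGAAGGGAAGC	first
32869968	TGTGATGGTTGGCGTGACTTCATTC	first
32877081	TGACATTTACGGACAGCATCGG	first
32327580	GAAGTTGTGCGGTGCATTCTGGATA	additional
32335279	AGAGTAAGACACTGACCCGAAACCG	additional
32344111	GGTTGTTTATCCAGAGTGTCCGCA G	additional
32352587	TCTGCGTCGAGTGTATGTGGTAGAG	additional
32359757	GCAACGAATCTGTGTAAGGTGACGA	additional
32368565	AGGCTTCCAATGTCAACAGATCCCT	additional
32375887	CCAGGCACTACTTCACAGTTTCAGG	additional
32382569	CACACGCTGATTTGATGCTTCTGGA	additional
32392099	GGCTGGTAGTGTCTTTGATGGAAGC	additional
32399141	TGGAGTTTGACCTCACATACCTGCT	additional
32407627	AAGGAAGTGACCAAAACAGCCCATC	additional
32415234	TATCTTCACACCACATCCAGCCCAT	additional
32423604	ATACCTGGCTGTATGCTCCCTCATG	additional
32430251	CGGTCATTCACAAGCGGAAGAGATG	additional
32438734	AACGAACTTTCCACCAGCAACCATC	additional
32448247	ACATGCAACCCAAATAAGACAGGAAGT	additional
32454980	TCTGCTGACTTCCATCTAACTGTGC	additional
32462988	GTGACATAAAGCCCATAACCCTGCC	additional
32470115	CAGTGATCGTCTCATGGGTGTCTCA	additional
32479464	TGTAGCCCATGCCCTGAATGAAGTA	additional
32490870	TCCCATACCTGCAAATCCTTGTCCA	additional
32495691	GATGTGAATAATCGGTCCTGCCCAC	additional
32503310	ACGTGACTGTGCGTCTATAATGGGA	additional
32511589	TGAGACATTATCCACCGACACCGTC	additional
32518509	TGTTGCAGTGAGGAGAATGTGTGGA	additional
32529058	GTCTTGACGCCGAGGTATTGTCTCT	additional
32535546	AGGCTTTAGGCACTTCATCTGGTCT	additional
32544250	ACCGCTGCTGAGTTTCGCATCTATA	additional
32890292	ATTGCACTGACCTCACTCTGTAGGG	additional
32893147	CTGCTTCTCGAATACCCGTCCAGTT	additional
32901203	GTCACACACTGCACTTTCACACACT	additional
32909819	ACCTCCTCAACACTGACTTATGCGT	additional
32915780	CCACTGAAGATGCGTCATGCTACTG	additional
32925279	GCAGATGCTTACTACACACACTTAC	additional
32933665	CAGACTCACAATCATCAGCCTTTGC	additional
32941519	TGCAAGCACAATCATAAGCCAAGTT	additional
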