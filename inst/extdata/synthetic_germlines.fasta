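>IGHV1-S1*01
AAGAGCATACTCATCCCTTACTGTAACATTAGCTCGTTACGCATTCAGCGGACCGACACGCCAGCGTGTTTGTGGTTTCGCTGTGGTGTT............ACTCTTACTCAGTATTTTTGGTTTGTTGTCGGTCCGGCTGAGCTGCCGTTCAGGCGACTTGACTTAGATGCC......GCATACTGCAAATATAGCAGCAAGTTTTACTGGGATGCCCAGGAGTGCCGAGGCGGCCATAGTAAAAGAATTGAAGATCTGGCGAGACCCAATCGACAACTACGTGATAAACCGGAGTCCTTCGGTGCCTGT
>IGHV1-S2*01
AACGTCCAAGTTTCCCCCATGGTGTTTCTTAGGGACTTCGGGTCGTGTCGCAGGCTGTACCGCAACTGTCGGCCCTCAACTGTACTTTTGCGG......TGCATTGGCAGCTCGGGGTTGTGGAGGGATCAACGACCTACAGAAATCGTACACCCTATGGGCGAAGGTGGGCAC.........CCTGAGGCTATCCCCCGTCAGTTTTCGTCCTGGATATCGCCTAATCGCATGTTATCATCGGTTGTCGATCGCGCAGCATCGTTTATACCGATAGAGAGGTCGCGAAGACAAGATTCAACACCGGTTTGT
>IGHV2-S3*01
AGCGGGCAGACGACGCTCCTAAGGAATGACAGAATGGTAGCCTTAATTTTTAGTCTTTTCGAAGGGTGTTGTGGTGAGCTAAAGCTGTTC............AGAAACACAGTACTAGACTGGCGCGCGCAATGTGCCCTTCACTCCGGAGATCGGATAACGAAAACGGGGTTT......GGCCTTTGCAGCGTCTTACGACAGTACCCCGTCATATGTGTGGGATTAACTTCGGCGTGGACCAGGGCCCATCTGGTGAAGGTGTCAGGAGAACTCGTAGAAGAAGGCACGACCAAGATCCTACGAGTCTGT
>IGHV3-S4*01
TCAAAGCACACTATTTCTCTTGCCGTAATTTATCAGATAGCGTCGGCATCCGTAGCAGCAGTACTGTGTAACACGTTAGTGCTGGCGTTA............TACAACGCTGCGTCGTGGTGGACCTATCAGTACTACGCAGCCCACCCGTGGCCTGCGGGTATCTCCAGAGCG......CCAAAAAGATGCTTAACCTCTCCTACTTCTCATGACAGTTTGCTACACGAGCGATATCGGATTTGGCTCGTTCGGACGTGCATGTGCCAAGTACAGGCGTTTCACTCATCCTTGGAGCTGCAGCAACGGTGT
>IGHV3-S5*01
GCCTGTAGCCTCGAGCCAGCCTGTCCGCTTGGGGTAATCCACAGTCAGTGTATACTCGAGCTAGACTGTCCGGAGCAATGTCTGACATCGCTAGGCGCGGACGGTGCAAAAGTAGTCAACTGGGGAGTCCAGTCGCGTGAAATATTATGTGAGAGATTTGATACCACAGATGTCGCTCTCCTCAGGATGAACTGCGTTCGCTCCCGAGCCGTCGCCCTGACCCCGACTGGTATATATTCAACCCTTCCACAGTCACTCACACCAGCAGAACCCGTAAGATGGACGTGTCGGGGTGATGCCTCTGGCCAATGT
>IGHV3-S6*01
ACAGATGTGTCTGTAGACTACTGTGACAGACGACGACCGGCTCTGCACCTTGGGTGTGCATTGAAATGTATTACTGTACCTGGATGGACG............GTTAACCTGCTTTTACGTTGGGTGGACAATCCCTCGAGCCTCTCAGGACCATACGGCCCTCCGTGCTATATC.........CCATCTCCCGCAGGTAATGGGAACGTAAGGGAATCACTAAGGCCTATCGAGCGAACCTATGATTCACATGTGTCATTTGAAAGGTGCGCTGTAATTTTAGAAGAAGCTACGCCGTTTATACTACCTTGT
>IGHV4-S7*01
GTCCTAAAACTATACTGGAAATTGCGCAGACTAGTAGAGACCGACGTCTACAAGGTACTAGGGAAATGTGGGCGCCCTTTAATATTGCCCCCC......GCAGGCAAAACCCATCTCGACTGGAGTCAGCGTGTTCTGATTAAGGATAGGGGCCTCTGTGGGGTTTATGATGCA.........TTTGGCTTTACCGTGGAAGGCGTAGCCATAAGCACGACAGGCCATTCACGTACATGTCCAGTAGGAATAGGCTGGATAAATTACTCGACCACCTTCATGGGAGGAGGCCATAACCCCGCAATAACCTGT
>IGHV4-S8*01
AGTAGTTATTTACGCGATCAAAACTGCGCGTGTGGACAGTGTCAGCCGTTCATGAGTGCTCAGAGGTGTATAACAAGTGTAGTGCCACTTACG.........TTAGAGAGATCGCTAGAGTGGTCATTATGGCTTCAGTTCATCCTTAAACGAGCCGACGTCTGGTTGCGCCCA......GACGGTGTCGCCCGTAGTCGGTGGAGGAGGGAGCCCAAACCCAGAGGTATCTTTCTGAGCGATACGTTAAATAGCCCCCTTAACGCGGCGGCGTTGAGTATCGGTCTTTTTGACGTTGTCGGGGTCGAGTGT
>IGHV5-S9*01
GAACTGGCCTTTAAAATCGTCGGTGCCGTCATTACGGCGTCCTCAGTAAGTTTCAGACAGGTAGACTGTCTTAGGTTACTTAGCATGGGC............CTCAGCCGGTCACGGGGGTGGCAGACCGGTCTTGAATGCTCGCGCTGGCTGTTTTCCAACAGGCCAACTGCC......TCGCGGGTATTGCGGCTGGTTGCGGTATTCATATCGCCAACACGATCCCATCAGGCCGCTTCTCTAGCCTGCAGGACTTACACAAAGACTGACTCAAAAACCGAGGACTTCCTAGGACTAAAGGCGCATTGT
>IGHV6-S10*01
TTGTGCATATACGTTCTAGCTAAGACTCATAGTGTCGAATGCTGTGCTCCACCTACCGCGCGTTTGTGTAGACCTGCGTTCGGAACCTCT............GCGAGTCCAAAGATCCAATGGGCTAAGCATTTAGCTCTGTATATGGTGCTGGTGGCTCTCATGAGGTTGAGG.........GAACACAGAGTATACCCGATATCGGTGGGGTTGGCAAGGTCCATCGTAGAATGGCGATCAACGGGGGTTTTAGATCGTAACGGACTTGATTGCCGTTTTCGACAAGAATTCCTTTGTCACCTGGCTTGT
>IGHV1-S1*02
AAGAGCATACTCATCCCTTACTGTAACATTAGCTCGTTACGCATTCAGCGGACCGACACGCCAGCGTGTTTGTGGTTTCGCTGTGGTGTT............ACTCTTACTCAGTATTTTTGGTTTGTTGTCGGTCCGGCTGAGCTGCCGTTCAGGCGACTTGACTTAGATGCC......GCATACTGCAAATATAGCAGCAAGTTTTATTGGGATGCCCAGGAGTGCCGAGGCGGCCATAGTAAAAGAATTGAAGATCTGGCGAGACCCAATCGACAACTACGTGATAAACCGGAGTCCTTCGGTGCCTGT
>IGHV3-S5*02
GCCTGTAGCCTCGAGCCAGCCTGTCCGCTTGGGGTAATCCACAGTCAGTGTATACTCGAGCTAGACTGTCCGGAGCAATGTCTGACATCGCTAGGCGCGGACGGTGCAAAAGTAGTCAACTGGGGAGTCCAGTCGCGTGAAATATTATGTGAGAGATTTGATACCACAGATGTCGCTCTCCTCAGGATGAACTGCGTTCGCTCCCGAGCAGTCGCCCTGACCCCGACTGGTATATATTCAACCCTTCCACAGTCACTCACACCAGCAGAACCCGTAAGATGGACGTGTCGGGGTGATGCCTCTGGCCAATGT
>IGHV4-S7*02
GTCCTAAAACTATACTGGAAATTGCGCAGACTAGTAGAGACCGACGTCTACAAGGTACTAGGGAAATGTGGGCGCCCTTTAATATTGCCCCCC......GCAGGCAAAACCCATCTCGACTGGAGTCAGCGTGTTCTGATTAAGGATAGGGGCCTCTGTGGGGTTTATGATGCA.........TTTGGCTTTACCGTGGAAGGCGTAGCAATAAGCACGACAGGCCATTCACGTACATGTCCAGTAGGAATAGGCTGGATAAATTACTCGACCACCTTCATGGGAGGAGGCCATAACCCCGCAATAACCTGT
>IGHJ1*01
CTGCACTGGCTAGACGATCGA
>IGHJ2*01
CAAATGTGGGGGGTGACGTTG
>IGHJ3*01
AACCTAGATTGGCCGGTTACAGAT
>IGHJ4*01
CTCGCTGATTGGTGTGATACCGGC
>IGHJ5*01
AATGGACGAAAATGGAGTTTTACTGTT
>IGHJ6*01
AATTGTCAGCAGTGGTCGTGGACGACGGAAAAC
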