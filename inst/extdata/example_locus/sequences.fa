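>left_arm
CGCTGACCTGTCCTGCCGGGGTCATGGTCACGTTCTTTAGGATGTCCAACCAGGAGATGGCAAACTGGGAACTCGACTGC
TGGGCTGCCAGGGTTGATTCCAGATATTAACGACTACCGTTACGGGGGCCATGTCACGCTGTCGGGTCAGCTGATCTTGC
CGCTCCTGGTACCCTGTATACTTACGGCGAGATATCTCAGCCAGCATCGCGCACTAAAACGTCCCCTTGGTCTAGGCCCA
ATGACGTTGGCATCAATTGGGTTCCCTTAGATATGTGCATTGCTTTCTATCCTGGAGCCCGCCGGTTCTTGAGAGTCTGT
TGGACGGGACACACCTTGTAAGGAGGAGGTAAAATCATCCTAACGAAGCGGAGTAGTGTTGAGTGGTTCAGCTATGAGTG
AAACCGTTACACATTGGATACGGTCATTCGAGCCAGGCAAAGTCACAAGCACTAAATTATTGACTATCAGTCTTACAAAA
ATGGCCGAAGTGTCCACTCGCTTTCCGGACGTCTTCTAGCAGACTAATTAGGATGGCCTCCTGGACGAATCGCGCGTGTA
ATAAATGGTAAACGATGACAGCGACGAACTGACACAACCCCTCCGAGTGCATCCACTTTAATACGTCACAGAGTATTTAG
CATAAGATTGGTTACACATGTTTTAAGCCTCTGGATGTTGTTGAATTATCAGCATTCCTTAAGTACCACCTGATTACGTC
CAATCATTTCCTTTACTACACCTGCCGCATAGGATTATTCGCGTCCCCAAAGAGCTTAGGATCTGCTGGGGCATCCTACT
TACCCCTCACGAGCAGCACTTTCACGCCTCTTATCCAACTGGCAAGCCTCCGAAACTAACTATTCGTTTACCATGGGACT
CTTGCCCCTCCTACACCGCCGGCCCCTGGTCTGGGGGAACGGGGGCTATTTATGCGGATCACAAGTTTTTATTGCATGGA
>right_arm
AACGCTCTGGGAGAAGTACACGGCAAATGCAGTATTCGTTATGATATGGCTAAACTAGCTCAATTGCTACCCGACATGAA
CCTTGTATGAGACCTGGAGCTCGGACAACATTTCGAGATTAAGCACGAGCTGTTTTACAACGCGGAATATTCCAAGTTGT
ATCGACGAGCCTGTGATATTCCCCGGAGTGAGAAATTGATACGAGGGATGATCAAAGTAGACACGGGTGAGGCCAGTGCC
AATCCTACCAACACATTTATATATGAGCGCTATTGTAAGAATGCGCTTATTCTGATGTCTCTTTCCAGCCCCTTCATAGG
CTTCCCACAAACCCGTCGATCTGATAAGTTAGCATGGTTAACCTCTGTGTGTGAGCAGAATTTTACAAACACCTCTTTTG
TTCGTTCTGTTGACGGCTCGGCAGTGCTGGAGCGACGTTGAATGCGCGGAAATCCATGTAGCTCGGTCTGGATACCATCC
AATTTCTACCCTTCTCAAGGTCGTGCTTCCGTCATTGTGTGACCAAACATCAAAGATGCAGGAGGGTCCTGTTTAACAAC
GCTTCATCTGGTAGCAGAAGCGCGAGGAGTCCTGTGGAATTTGTTCTATATGAGATGAAATTGGTAGCGGCACGAAGATC
CTAACTGTTGGTCTATGTCAGCGCTCGAACGCGGTAACCAGACTTGAACTTATTCAGACGCCTTAACTCTCGTACTCTAA
CTAATTCACGGAGCTCACCTCCAGGATTCCGAGCGCTCTTTGAACGGACGGCAAGTGGCGCTCCCGCCAAGTGGCCAGTA
TAATGGAGGCTGCCCTAGAGGGTAGCATCGCTAATGACGTACGGCACTCGTTTAGAGCCGAACTCGGAGTAAGTATACGG
TCGGTACCCCGTCGGTGAACCGCAAAGCTAG
>payload
CCATATATACAGCGAACTCCCGAATGGCTATCAGGATTGGTTGACCGAAAGATCCAGCCCAAAATCTTGATGAGCTCAGG
GCCACCCAATTGTCGAAGAGATTCCGCACTATTAATACATGGGGAGCAATGGGAGAACCGACTCTGGTAGGTTACTTCCA
GTCTGAACCGCTGATCTGAGAATGTGGAAACTAACATCGGGAGTGAAATAACATGGTATTTGCTGGCGGCTCCCCTAACG
AGGTTGGATG
>wt_insert
TGTTACAATGAGTTAGGGATACTTTAGCTGCGCCCCATGTACGGTTTAGGATGCGCTCTCGTCGAGACGGCAACGACAAA
TTGCCGACGAGACGTCGCTAAAAAACCCTGAAGTTGGTCCGAAACCCTGATAAATAGGTC
>left_flank
GGGTTCGCATATCCTCCACTGCACAGACCGTAGCCATGGCAATCCTTTCCCTCTATTATTCAGTATCACTCAGAACGTCA
GCGTGTTCAAGTATATAGGCGTTCCAGTGCGGATGGGCTCGCGGCGCTGGGCATATGTATACTTTAGACG
>right_flank
GACTCTCTTCCGTCGCTCAGTAATAGTATATTAAGGCTGGACTGGAGGCCGTTACCACTGAATCGTAAGTCTCTGCGTTT
ATCTATTGGTCTGAATCTCACATTGGAGCGAGGGGTTTTCGCAGTCTGGCAGACGCGGGAGGCCCCCCCT
>itr_d_region
AGGAACCCCTAGTGATGGAG
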