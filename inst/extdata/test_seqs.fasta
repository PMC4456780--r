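>demo_1 synthetic length=548 gc_target=50
CTTGTAGGAACGTACAACTGAGATAGTCACCATGGCAGAATATGGGACTTCGTTAATACGATCCCCGCTC
GTCTCGTATCCCGTCCAATGTTTTCCGAATTTCTAAGTTCGTAGGTTTGAACTATTAATACATCCGATAC
AGCTGAGTACCCTATTCTCGGCCTGGGGCATAAAAGGTTAACGCACCCCTCTTATAGCGAGGGTTGCGAT
GTAGCTAGAGCCCGCGCAACATGCTCCTGCCGAGCGTCACTTTTCGATCACAACAGCAGGGGGGCCAGCG
CGCATGGGCATCCGGCGAAGCGGCAGCCAGTAAGGCGTAGATAACCGTGTGAGGCAGCCAGAAGTCCTGT
AGGTTGATTTAGGCGACTACCCATGGGTACACCATTCTGAATCCTTGACAGCGCTCTCCGAGCCGAATCG
GTTTTGCACGCCGTAGAGGCATCGGTTGGGTAAGCACCTGCGAGCAAGGTACACTACAGACCCAGAGGCA
GCCCCTACATCAGCACGTGCGGTAAACTTCAGGACATGCCTTCTATCTATCGGACTCC
>demo_2 synthetic length=564 gc_target=50
CAGAAACCCGGTGTATCACCTCCTTCATTCGAAGTGAGAAGTGCGGGAGTGACGTGTTGAACCGGGTCTC
TGGTGGCCCTTCTATGCTATTGGAACAATTGCCGGAAGACATGAGGACGCCCGGGGATAGACCTTTCAAC
TTAAGATCTATCGGTAAGTATGGCTCTCGGAGGGTGAAACGGTTAATTAAGCAAGCCGCCGTCAAATCCT
TAGGTGCGCTCAAAATTGCTCGTGCAGTCTGGCACAACTTCTCGTCAGTTTACCTCTGCCACCCCCGCGT
TGTACAACTTCGGACTAGGTCTAGAATGCGACCGGAACAGTCGATAATAACCCAAGGTGGAGCTTCCGCT
AGCTCGGAAAAATCCAAACTACGCGGAAAACCGCAGTCGAGCTTCGGGTGTTATTGTCACACCACGGTTC
CGGTCGCGAGCACGAACAACCTCGCACATGCTTCAGTCCCACGAGACGGCGGCAAACCCGTATGCAGGTT
CTAACACCTGATTCGCACCGTACGTTCGACTACCCGAGTTCATTCACATGTTCATCTTCGTAGAATGATC
CAAC
>demo_3 synthetic length=652 gc_target=50
ATATGAATACGCTTCGTGCGTGAGTCCCGGCACAATAGTACTGGGCCCGTGCTAACCGAGAGCTCTAGGG
ATTGCATCCAGGGTCAAATGTAACGATGGCACTTGAATCATACGAATTGTCAGAAGATACATAGCTCTGG
ATTTCGTATAGGTCGTTCTGGAGGGCTTTCTCGCTACTGTGAAGCCATAAGCTGGGGCTATGGAATAAAA
GTCAATTCCTTAGTTGACGTTCTCGTCCGTCTACGAGGCACGTGGGCGCGACACCTGCTCGGACTCTGCT
GTCTGCCGTCGGGCGCGTCGAGGAAGAGCAAGAAAGTGACGTCATGTTATAATTGCACCCCTTGCTTGCG
GACGAGGAGTACAATCTCACTTCGGGTTTGCCACAGTTGCGTCTCACTGTATGGTGGTTAAGAGTCACCT
TAACGGACTATGATGTTCGGTGAACCTCAAGGAGCTTGCACTCTCAGGCTGCACCCTTCCTATACTTGAC
TGGGATAATTACAACAATGCGCCGCAACCAACTGCGCGAGGACCACTTGGAGATTGCAGCTCCTCGCACC
AAAGCCGGCTTCGCACAACAGCCTGGTCCTAGAAAGCAGGATTTCTGTAGCGTACACGAACTCGCTCGTT
GCTCTACAGCTCCACAACGCAA
>demo_4 synthetic length=573 gc_target=50
TTTTCTGAGGCAGGGTTCGTAATGCACACAGGATTGCATCGTTTTTCCATATGACTCAACAGGTTTTCAA
TGACTTATAAGCAGACAATTAAGTAGTTACTTTAGCCCCCACCATTGCATACGGGACGCAAATCACTCAT
GAGACAAATAATGCACATCACATCGCTATCGCCTCACAGTTAATCGACCAGGTACGTCGACTCATATATA
CGGGGATATTACAAGCCGAAGTAATTACGGCTTCACTAAGTGCATGGTACGCCCCTCGCACGAAAACGGT
TCAATCTCTTCTTTATCGAGTATGGCACTCCCTCGCCTCTTGGCACCTGTGTTTGTATTTATAAACCAGG
GGATAGGCGGCTACTTAGCATTGCATATCATGCCTCCCATAGAGGCTTCCCGTCCCCAGCATAGACCTAT
GAATCGGAGGTCGGTGCTGTGGTCGACATCTACTCAGTGCAATCATTAACCACACGCGTCCGATTCTGTG
AGTTTACGACGACTTTTTACTATTAAAGTCGGCCAACGGGAAGTTTAAATAAATCCGCATACATAAATAG
CCGCGGGAGTATC
>demo_5 synthetic length=645 gc_target=50
TTGATCTATCAACAATTGCCGCGCCACGGGGCGGCCTAAAAAAGTAACCACTTATACCTTTATGAAATCG
AATAGGCTAATCAAGCGAATCGTATTTATGGGAGCCCTGGTCTTTTCTTGTGACGAAAGAGCTCGAAACG
GCGTGCATAAACGGTACAGGATGTCATAAGCGGTTCACGGATGTCGCCGTGTGAACTCGTGCCACATTTC
ATTTAATGCGTTTTCGGGAACGACGCAACTGTTAGATAGCAGTCAACCGCAGTGGAGGAAGTTCCCAGAC
AGCTGGGCCAAAAAGAGGATCCAAGCGCGAAACTAAACCACGTCCGCGGCGTATGATAATCACCAAGCCG
CCAGGAGTGGAAGGTTTGCCGAGGTGCCAAACCTGACAGAGATTCGTCTTCTTCTAGGGTTTTGGCATGC
GCAAAACACGCTCTCTTGGCTTGGTCGTCGAGACCGAACAGCGCGCATCAGCAACAGTGTTAGGGGAGGG
TTTATTTCTACAGCCATTGAGGCAGACTGATATGAATTTGACATCCACACACCGACCCTGTTGTATTCCT
AAGCTGGACTGACATGCTCCTGCAGGGTAAGCGGGATGGGGGGCACATGCTGGTACTACCGTCCGGAACA
CCAACAAGTAATAGA
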