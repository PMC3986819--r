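>r001
ATGCTCGGGGAAATTGAGATGCGCTTCCTGAACTCCATTAAAGCGACATCCTACTTGCTCCCAACAACGG
GTACTCCGCGCAGCTATTCTTGCACTTCAGCACAAGCTGAAAGTGCCCAACGTCGGATTGGAGGGCCAGA
GTATCGGGCGTTGATGCGAGTCCTACCCAGACTGCCGGTCCACTCGCTCGGTAATCCACTCAGTCAATAC
GGCTATTACCCAAATGGGCGTGGGGCCGCGTGTGCGCGGATGTACATGGTATCTAGTACCCAGCACAGTG
TTGTCGACGTGCGATGTGCCCTGTGTATTGATAGAGTCCGTAGGAAAGTATTACCACGACGTCACTGCCT
GATGATGGGTGAGCTTTGTGTCGGCCCTCAGGACAATTTACATGCAGGTCGTCTGTCGCACTATAGTTAT
ACTAAGACGTTCCAGGCATCCAGGAAGGCACCCGTTAACACGATGAGCGTTCTATGCTGGAAACAAGGTC
GCACTGGCCTCCTGTTTTTAACGGTTCAAAAGCAGATCGGGTGTCTCAGTTCGGGATATTATCCACCGTT
ATTACTCATTGAGTCGCCGAGTTGCAAGTTGCTGGCTATTCAGGACCTTATCTTCGCTGCGTCCATAGAC
CGAGACGTAAAGGTTTATTTTGCTAAAGACGAGCTCCAAAAGAGACACGAATCGGGACTAAAATTCCCTG
TTAAGTCGCATTAG
>r002
ATGTACCGTCCGTGTTTGGCGTTCTACGACAGCTCTGTGGTTCATACCTACGGATGGCCCCTTGGTATTG
TAAAACAGCGCAAATGCGTTCGGGCGACCATTATCTGTTCCGTTGTGAAGGTGTACTGGGCGTTGGGTAA
TCTCTTGTTGTATCGGAAGCGGTCATGTACTCTATCCCAATCGATTTGTTTGACAGTCGTGTCCGACATG
CGTCACCGATTCGGGCTAGCAGCATACGAGGTAAGAGACACGAATTGCGACAAACAGGAGCCTGCAGTGC
TCGAATTACCATTTACGTACTTGGTCATATTCATAGGTCTAAAACGAACATCCTGTTGCACGCGCATAGG
GCAGTTTGACGCCAGACATACACCTCCCGACTCATTTAACGTGTCGGAAGATTCATCTCTTATTGATGTC
GCTCCCGGCTTACGCCTTATTAGCCTGTTTTGA
>r003
ATGCTAGCCATCGGGCTGCTTTGGGTTAAACAGTATAGAGGAGAAAGATTAGCGTTACATCGCTCTATCG
CTCTGACTTGTCGACTAAGGGGATTAGTCCCCGTGGCGTTCGCGACCCTCCTTTTGAGGGCTCTGTACGA
CACTAATAGTATACGCATTGTGTTGAGAACGTTGATGCGTTTTTCGATGGTGGATGTACACCCGGTATTG
TATAAGTGCGCTCCGAGAGTAGTGTCCACAATGGGAGAGATCCCCGCACTGATTACCGTGTGTCATCTTT
ACTCCATGTCAAATGTTATGAAGTCCCCCCTGAAGAACATGAACGTCTTTAGGTTTTACTCTGTCTCTGT
TGCGACAGGAAACATATCTGCTTTGATCGGGGACCAGACACCAAGATCAATTAACCGATTGCTCCGACCC
GATGTCGGTCTTCGCCCAGAGTTCGCATAG
>r004
ATGGCGGACGTACACCCAGCTCGACCTAAGCTTACTCCCCAGCAAACACACCCCGTGGGCGATGGTACAC
ACGTTGGTGCTTACATCGGCTGGCACTCTGGGACGAGCCTCATTAGAATGAGACTAGTGAAACATCTCTC
GTCTGGCGTATCTTTACGATCAGTGATTCTCGCAGGAGCTATCGACGTCTCCATATGCAGACGCATAGTT
AAAACATGGGGTGCTGATGATCGGAGCAGATACGGGGGATCATCCACCCATCAAGAGTTCATACGGCAGG
AGGCCAATTTGGACGCTCGTGGCCCGTGTAGAGAAGTACCGTCAGATTGTATGTTTGCTGCTAAATATGC
AGGCATAATGTTTCTAGTGAAACGTTCTACACTAGTCTGCTTAATCGGGTTATACACTGCGCGTGCGCGC
GCTCTACGTTTGCACGGACGTGTACAAAAGTCTAATAACGCTGCTCCCCTATACCCGGACGGTAGTTCAA
ATAACCCATTGCTAACTTTGCTACCACCGCCACCGTGCGGCTGCGTTCGTGAGCTCGGCCGAATATGTTT
GCGCAGTTCATCCGTACGGTTAAGCGACTATGTTTATGATCATGGGTACCCGCCGTCTTAG
>r005
ATGCATAGCTTATACGTAGCGACCGGCTCGACTCCGATGACTCCTCTACATTCCCACGTACAGCGCTCGG
CTCCCCTGAAAACTGGCCCCTTAACTCGGGAGTGTCGAATGCAGGCTAAGTATTTTGGTCCCACAGTTTC
CCCCTGCAGCCAGATCGTTATGGGGGTTTCCCCACCGACATACGCCAGTCGATACGCCTACAACAGAGTA
GGTCGGCACCGACTGCCACTGTACCCTGGCAAGATATTACATCATATGAGTGGTGGAGAGCATCGTTGCA
GGCTAAATTCACGGCGAGTAGTGAATTCGCCACGGAGAATGCTCCTGTTGGCTCGTGGTTTCACGATGAA
TTTACTCGGTGGCTTTTTAGATGCACAAGCGGGTTACTTTAAGTTCCGACCGAGCTACGTCGATCGGGAA
AAAAGTCAAGTCAAGAATAGGTGGTGGGACAGCCGCTGGATCATAAAGGCCTGCAGAAAGTTAATAGATC
AACCATTGTGGCAACGAAGGTCCGTCCCACCTTATACTGACGACAAAAGTGAGACTCTCCGACCAAGGAC
ATGTGGGTGCCCGAAACCCGACAGCTCTCAACCCGTTCTTGAGCGTCCAACAACAACACCGCTCGTCCCT
CAAGTAGGGGCTCGAGCTGTTTCTCTGTACCATGAGCATCGTTCAGGCCCCTACTTAGAGATAATGAGAA
TGGGAGGGGCCAGTGGGAAATGCCATTTACGCCTAGCAATAACTACTATTTGGAAGCCCATTGATACGAG
AAGAGGGAACAGGCAAGCGACAGCAGGTATGGAGTTCCGGCCTATCGGAAACCTCTTTGAGGAGAATCGT
GTCTATTTTGTAAATACCCAATTACCCACATGTGGGCATTGTACCGAGCTTCAATAG
>r006
ATGAGTTTCCAGTCTAGCCGTGCGTGGCAAGGGGGTCACCCTATATATAAAACTATGGCCCTGGTCAAAT
ATCTACGGTCGCAGCTGGACGAGCACGACACCTGGACCGCTTATTCCTTACCCCACCTTATTCGCACAAC
AAGCGTTCCTATATTGTGTTCTACGTTTCCTTGTCCAAGCGAAGAAGGAATATTAATACCGTCCGTCCAA
TTGGGCATGTGGTTGCTGACGCATAATCACGGAGACCCTGCGCCCAGACCCTCCAACGCGCCGACTTGTC
TATGCGATGCACAGCAAGATCAGCCAGTGGACAGAAGATGTTCTTTGCGATCGAGTTGTGCACCTCAGTA
CCCCATTCTCGAAGAGACCATCCCCACAACCGAGCAACTGTTTAACTGCAGAGAAGAGTTAATACTTGAC
GCTGTGTATGACAAAAGGCGTGTGTTTTGA
>r007
ATGCATGAGGTGCAGGCTTTTAGTTTCAGTCGTCGCGACTCCCCCGTGCTTGGGAATTTTGTGACTAATG
TAGAAAACCACTCAGACTGCCTCAACTCCTCGCCGATTTTGCACCGGCTATCATCCGTAATAAATGCACG
TGTAATTCCGAGGGTGTATTGGTATTCGCCATCTTCAACACACGCGATAACAAGAATCGATTGCGAATCT
CCCGATCAAGTCTATTACACCTCCCATACCAGGCACTTGATACGACGACTGAGTATCGGATGCGGAATCG
AGATGGCAGGGACGATCATCTCTCCGGAATGCCCTTCGCAGCTCGCAGCGGCCATGTATACTAAACGCAA
CCGGTACTCCGCGTTTGTGGCGCTATTCTTCGCAGCGACCGGTGCCTACTCGACATACGGTGTAGCTGCC
CTTGCGGCTCACCTAAGTATCGCGACATAA
>r008
ATGGAGGGCCTCACTCAATCCCAATATACAAGCAGACTAATTACGCGAAGTGAATCCATAGCGTCGGGTC
CCGGCTCTCGTGACCTCTATCTTGCGTGTCACCCTCAGCGTCTAGTATATTTTAGGGCAAGAACCTACCT
TGTTCGCATTATGAGGCCTAGATCAAAGTACTCTGACGCCTCAAACTACGTATCGATGCTATTCCTTAGG
AACATACGCAACGTCGTCCATTACACACCCCTGCGGATGTGGGCTTTCAGCTTAGGGAGCTATATAGTTG
TCCGGTCCGACCTTCTGCATAAGATTTTGCAGTACAATTTCCTAGAGCGGGTAATACTTTTGTCTCCGGT
TAGTGTGAAGTGCAATCGTTCCCCGCCAAGTACGGACGCAACATACGATCGGAGCTACATTCCACAGTTG
ATCGGCGACGTATCCAACATTAACGTCTAG
>r009
ATGTTGCTGACGTGGTACGATGGTTTACATGCCGCGTTTCCCCGCAAAATGCCAGTGGGTGTGATTAGTC
GAGTCCGGGCACGCACAGACAGAGTAAATGGCATAGAGCTAGGGAGCAGTCTTAGAACCTATATTTATCA
AGTCCCGCGCAAACCTACTCTCACAAGCATACGTCATAAGAGTGGCCTGAGGTCAGGGGTTGAATGTGTA
ACCACAAACGTAAGTCTGAGCAGCATAACTGATCCACACCTACGTGAGTCTGTAACCGGAGCATTTGAAG
CAACTAATGTATCCGAAAATTACGTAACCCATTTACCCGCACTCATATCAGGTAGAATACTCTTCCAGGA
GATGAGGTGCGGGGCGGGAGGTGTTCTTCACCGTAGAGTGGCCCGCTCGATGGTATCTAAGAGTGGCAGG
ATCGACGATGCTCTGACTTCCCCACGCTAA
>r010
ATGTCGAGTAAGCCCTCTCACACCCCCAGATCCTGCATGAGGTACGCGACCAGTCTACCAAGCCAATGTG
TCTCTCATTCCCTGAAATCCATTCGCCAACACGATCGTCGTGCTACGCATTCTTTCCCATGTAACTCGAT
CGACGAGGACAAAAAGATTGCACACGCGTCGCCGGGACAATCCAGCGCCGCATTTGCAGTGTATGTTACC
CAGGGAGTGTCGACGTCCACCTTATGCTATGGCCGTAGTAGTCTAGATGTAAACTTCCCGGTAGAAGCAA
CTCTGTGTCATTCTCGTTCCTATCAGAGGCCACGTGTTGGCGGAGTCGCGTTGGTAGAGAGCGACTCCAC
AGACCGCGTCAAGTACCAACCTGACCTAGCTTCTTTATTGGGAGAATGTTGTGTCCCAGTGAGGGGGTGT
CTCCTTCCATGCAGCAGACATGTGCATATAACTAGCCTCGCTACACTCTACTTATCTGCTGCAATTCATC
GTGGTCGCCTTAGTTCGATAACGTTCTGGTCTCTCGCCCCCGAGGGTATAGCCGTCATCGAACACCTCCG
CAATATCCTTGCACGAAATAAGACATTCACTGGGTCGTGGAGGTCCCGACACCACGAGAGGAATTGTGGT
GCTGGCGTCCTCTGCGAGAGACGGAAACTGAATTTGCACCCATCTACGTCGAAATTTAAGACCTCTCGGT
GGTACAGTGCATTCCCTAAATCTGTCGGCCCTCTATTTAGTTGGGTCCTGGGACGAATCTTCGATGACCC
GAAGCCCCGGATCTCATAG
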