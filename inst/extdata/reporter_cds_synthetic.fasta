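>CAN1syn synthetic 1773-nt reporter coding sequence (coding strand)
ATGTTGATAGGTGCCCTTCGTTTACGTCCTTAGTATTAGCATGATTTTAAAGCCTAGTTG
GTGCTTGTTACATGTATACTATGACGTAGAGGGAAGTCACTACTGTCGAGGCTTGCAAAT
GCCGCTAGAATTAAGATTGGTCTTAATGGTAATAGGGAGAAGAAGTCGTGCTCTCAAACC
GCCATAGACCTAGAGTATAGGAATAACATTCCTTGCTTTGTCGGCCAAGTAAGTACTAGT
GAACCTAATTCTATAACGGGTATGGAATTCGTTCTTTAGCATCGGATTGCCACTACTACA
GCTACGTAGTGAGAGCGATATGGTGTTCTCTATGTGCCCTAGAGAAGCTCGATTAGTTTG
TGTGCCCCGATTGTCGCTCGGTGATTACTTATTACTTTAGTAGGTAAGACGGTAAGACAG
ATGCTAAGTATCTGGCGACTATATTTGCCATTCTCGCGACTCTTGTAGCTTGTCCTCTAA
CACATTTTACTATAGGACTAACGAGGAATACCGTTTCAATATTGTTTAAGTTTATGCGTA
TCATTGATGGCCCACGCTTGATCATTAGAGAGCATCCAATATCTGTTTATCGAAAATGGA
CTCCAAGTTCTACCGGAGAGTAATTTGTCACTTACGTAAAGGGTTATTCTTACATGGGAA
GACGTGTATTATTAGTATAACGCAGCTATGAGAAGTCCACACAAATTGATGGAAGACTAT
GACTTCATGATCAGAGGTCGTTGCGAATATATCCACGAATTGATGACCTGCGTCTTTGAT
CCCTGGGGCAATAACACATTGACCTACTGAAGACGATATGTTGTACCATAAAAGTCCCTT
CCAGATTGGTAAATTTAGGGCAAATATGGTACCAATTGAATGCTCTTAGAGCTCTAGCCA
AGATAACAACCTAGATCATCATGAATCGATAAAAGGGTCTAACTCAATTTTTTGTCTCAA
GGCGACCTTATCGGACAACCCAGATGCGTAAATTATTCACAGGAGTGTCCCAGATCATAC
TGTAGGAAATAGAGCATAAGTTTCCCCATCCGAAGGTGGGGCTTAAACAAGCGCAATACT
AGAGAGTGGAAAATAATCGTGACGCCACTGATGACAACTTGTCTGTGCTGTTGAGAACCA
CACCAGTTACAAGACCGGCGTCTGAGAAGAGTCCCGAGACCTGACAGTGAGTGTTTAAAC
CGGGTTATGGAGAGTTCTTCTCGTAATATTTTCCACGTATTAAGATCACAATAGCTTGCC
ATTTATTCATACCAAAAGATTTGAGAGTGTCTGCTTCAATCACGAATCTCTGGTTTCATT
GGGAATAACATAAAAGGATTTGTGTTGTTCAACAGTGTAAACCTTCATTACGTAGAAATA
TAGATTAACAAGCTAAAAGCCCTCTGCAGTGACCACTTATTGACTCAGTCTTCTATCACT
CACTCGTGATCTGTGAATGTGGCCTTATTAAAGTGTTTATCTGAGTGAATAGAAACTCGT
GTTAGACACTCGAGTCTATATACATGTTAATTACGTGTTACTGGTGTAATAGAGTCCGTG
ACGTGTTTCTCTTGAAAACCGATACTGTCCTTGGTAAATCATCTTCCCGCAGTACATTCA
AACATGTAGTTCGTGGAAATATTGTTGCACTAAAGGCGACTTATAAGTCTTCTCAGGAGG
CCCAAATCTAGAGTCTAATGGAGGTTAATATGCGATTATTTACGCTTCCGTTAGCACGAC
AATCATTGCAACTAATGAGACAGCGTTCTATAA
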