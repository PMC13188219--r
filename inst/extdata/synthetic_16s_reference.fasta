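>SYN16S_1 synthetic bacterial 16S rRNA reference (E. coli J01859.1-like coordinates; conserved primer loci real, variable filler simulated)
GTCCGTAAGAGTTTGATCATGGCTCAGCGACGATAGATTTGCCGCGAGCGTCCATCCCTCCCTGGTGCTT
AGACCGCAGTGAGGAGCAACTACGAAAAAACCGCTCGAGTCAGGATGTTGGCTCCGCGGCCCGTAGGAAG
TTTGGCGTTGTTTTCTCTTATTCAACTGACTACCGTAATCCTGTTCAGCCGCCAATAACTCTTAGTTGGC
ACTATACAATCCAACGCTCGAATTATTGACGTGCGAATGTACCGAGGTTTACCGGCTCCGTTCTCGGCAT
TTCCTAACTTCTGAGACAGTAGAGCACCAACCATTTCCCAAGGGATTACTATAGATTACTCCTACGGGAG
GCAGCAGCCGGGCAGACGTGGTGGGGGCGTGCTTAATTTGGTAGTAGTAACTCGAGGCGCATGAGTTTCC
TATAGACTCTAATGCTAATTTGGAGGCAACAGATACGCATGTATGCCGGTTTAATGACGCGCGAGTTTTC
CTTATCCGTCTGTCGCACGTGGGGTGCCAGCAGCCGCGGTAAGATCATGAGGAACCAGTCTTGTGCCCGC
CGGATAGCAAGTAGCAGAATCTATTCCCCCTCCTCTGTGCTCCGGTCGAGGGGGTAGTCGCGGACACCTT
GCTCCTTAAACACCTTACTGAGAGTATTCGACGTAAACTAACAGGTTTCAATTCGTCGAAATTAGGCACC
TTCGAGGACCTTAGGCAGTCTCATTACACACGGTCCTACCCGTGGTCCAAACTGACGATGATTCGGCTTG
GCGGAGAGCTTAGGGGATTAGATACCCTGGTAGTCCTCTGCTGCATTGTGCAGATTAGTTAGGGCTATCT
TTCCGAGAATTAACTCAGTAAGTACAAAGACGCTCAACGGTTCTGTGGTACCATTAGTGGTGAGAGAAAC
TCAAATGAATTGACGGGCATATGAATCCGCACTAGAAGTAACGACCGCCAATGACTATCATGCCGCCAAG
ACGTACATACAACCCTGAGAGCGTAATCTTCAGATGCGACAACGCGTCGGTCAAGATGGTATTATGGGCT
GCACGTCGATTGAGAGGTATTGCTGCCTCTGCACTAGTATCACCGACTAACAACGAGCGCAACCCCATCA
TTGAATAAAAATCAGTTACACAGACGTTAAGTACTGTAGGTCGACATGCTTTGTTGGCAGTAATCACTTT
TCTCACATTCATTCTACTGAGGCAACAACCAAACCGGGCTCAAGTTAATTATTGAATTGTAAGTGGGACG
AGCCTGGACCCCTAAAGGAAGTTGGGGTTATCCCTGATGCTGAACTTACGTCTGAGTGCGACAGTCGGGA
CAGGATGCTTAGTTGGCGCTCTTAGAGGTTATCGCGACTCGAAACTTAGTGCGACCGCTGACACTAACGA
GTACTATACAGTGTCCACGTATTGCCTACAGGGGGCAAGAGTTCTACGCCTCAGCTTTTTTGCGTACTAA
GTCGTAACAAGGTAACCGTACCCACTACCGCTCGTGCTCCTAGCGCGGTCCTATCTCGTACAACCGCCTA
T
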