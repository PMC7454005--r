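>hprt_synthetic 546bp synthetic wild-type target-locus amplicon (randomly generated; not the real locus)
TCTTACTGCTTGCTGAGGGCAATCATAGTCTGACCTCGATCAGCTCTAGTGACAGTAGTGTTAATAGCTG
AACCTATAGCTTATAAATAAAAAGATATTGAGGCGGCCAATGACCGCCCTAGTGATGGGTCTTCCCCCAT
CAGAAAACTTATTTGGTAAGTGAGACCTGAATTTCGGGTTCCCTGAAGGGCGACCTCACTGAGTGGAACT
ATCGATCCCATTGCCTTTTAACAGCACAGCTCTGCCCTCCTTGCGACCTTGACCATCTTTGGCCTCCTCG
TTGTACTCACTTGAAGAAGTACACCGACCAGTTTAGTCTGTGTCGTCGTACTGTCCGGCAGTTTCCTTAT
GGTGCCTGCGGCCGGCGGCGATTTTTCACTAGTAGTCACAACAAAGATCATCTTCCGGAACTCTGGGGGG
AACGTAATATCTAGTAGAAGACTTACCCCCGAGTGCAATCAGGGTCAAGTGCACTACCCAGATTGTAGGG
CCCTTGGATGACACAGCGAAATCGTCGTTTGCCGGGTGGGCCCCCTTGCAAAATTA
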