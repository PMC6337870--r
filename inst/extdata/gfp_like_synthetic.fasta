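>gfp_like_synthetic
AGACCAGGCGACGGGAGTGACTGTATCCCGCGCTGTTGTTCTGCGGACTTTCCACCTAACATATTGTGGTTCTGTATTAT
AATTGTAACTCACAACGTGACGGAACTGACTCTCGTTTTGTTCTATACGCAGACGGAGAGTTATCCGGAAATGGCCTCAC
CGCCAGCCCAATGGGCTAAGGTAACCACTAACTGTAACCGCTGGGGAGACCCCAGGGATAAGCCCCCGGCCAATTGCAAC
GTATTGTCTCCTATATTCCCCTGCACAAAGTTCAGGGTGTTGAGGTTTATGCGTCAAGATGATACTTATCTGCTTGTGGC
TGAACCCGCAAGCACATTGAAATTAATGCCTCCAATATCCACCTTTACTTGCTTGACGGCCCACTTGGAAATTAGGATGA
TTAACCGGGGCCTCACGGTTATGAATCAAAGCCTATCGCTGTTCCTGAGCCAGCCTAGGGCAGCACCTGCGTCACTGCCT
CTGCCCACTTATCATGGCATCAAGGCGACATGGGGATACTCATTAAAATCAAAGGAGGCAAATTTCTCTCAAGTACAAAA
TCGTAAGTGTGAATGGACCAAACCTTACATTATATATTCTAATATTCTCTACAACCGCCTCGTGGGGCAGCGAATAGCTC
CGATACGTAGCTATGAGGCGGATACCGCAATCGGTCCTTATCAGGTCACGATTTCAGGTATATCCTGTCGACGG
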