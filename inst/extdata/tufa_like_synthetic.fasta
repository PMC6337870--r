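>tufa_like_synthetic
GACCTGATGGTGCGAATATACATTGTCGGCAGTTGGTCCACTCAGTACCTACGCGCGCTGTGGTTCCGCGTGACCTCACT
GGACGCGGTGGCAATCCGCTTGGGAAGGCGCCTACTGACTGCTGCTTGTATTGCGCGACTGAGGTGCGAAGAAGCTAAGT
CCGCTTCTAAGGGAAAGTACCTAAGAGTACCCCAAATGCTGATCAGTCTTCGACTCTATCAACTACGTCTGCGAAAATTT
AAGTCTTCTCATCTGTTCATCGCAGAGCTGGTGAGGATGTTGCGACAAGACCGACTGCTGGAGCTGGCGAATATGATTGA
ACTGTGCCCTGAGCTGTATAGCCCGCATAGTGGAATTGTCGCGGAGGAAGGCCGTAGAGGCACAAAAGAAGTGGATCGAA
TAGGCACAACACTCCAGAAACTCCGTCTTATCCCGTTGCAGGTGCTGGCTGAGCAGGTCTTCGAACGAGGCTGCACAAGT
CGGAAGAATGGCATCCCAATAACGCTGGTAAAGCATGGGTTAAGGTCGTGCCTACTCAAAAGGTGTACACGAGATCTGCG
AGAAGTACGCCGCCTGATTCGTAGGGCAAAGACGCGCCAGGTATATCGTCGACATGAAAGTCGATGCCAGGCGCTAGGTG
GGCTGGTTATCGGTTTCCTGATAGGGACAGCTGCTTTGCTTGAGTCTCTACGCATCCGTGGACGCGTGCGTGCGCAAGCT
CGTAACCGCTTGCTGCAGATATTGAAACGTCGCGGGCGACTAGACGTCTTCTCTGAACGACGCAAGGTACGTGCTACGCT
GAAAGCCTGTCTGGTTTTTGATCGGGGGACTGTAGATGAATTGGAAGATCTGGAAATATACTGGTTAATCGACTCGAAGA
GCATCCAGGCGACTATTGAACGTCGAGTACGCCGATATTGCGTTATTCGCCTGAACAAACGCCATTGTGCGGAAGTAAAA
GGAGATGTGGGTCTGCAACTGTTATTGTGGTCTTGTCGCCGCGAAGAGGGGATGCTGCTGAAACTCATTCTGTGTACTGC
CTTGGTGAAAAGCTTGGGGGAGACAGTAAGCGTTTTGCTGCTACGCTTGCTGGGCGGAATGTACTGGTCATTGAAAGCAG
GAGCACCAGCATGTTTCGAGTACGACTGGGAGACTAAGGTTGAGTTGAGGGGGCGTCGAAGT
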