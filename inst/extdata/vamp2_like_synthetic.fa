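>VAMP2_like_synthetic synthetic CDS with the published VAMP2 wobble composition (85/117 GC3, 31/117 AU3)
ATGAAGCTGGAGAAACCCCGCGTGTACCACTGCGACGCCGTTCAGAGAGGCCGCAACACA
AAACCTAGCAACCTGTTCACCAAGAAACTGGAGCCCCCTGGACAGCACAAGCTGAAGTCA
CTGTGCCTGCTGGTTCACGGCGCCGATTGCATCGGCCCCGGCTTCAACTTCGCCGTTACC
GAACACCACATCCTGGTGACCCACACATTTTGCATCAAAACAGGAGGCGAGCTTCTGGGC
GACGGCAGAACATGCCGCGGCTACACCGAATACAGCAGCAAGCACTCAACAGTGCACACC
TCACAGTTCACCAGCAAACAGTTTACAGGCCAGGAGACAGAGAGATGCTAA
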