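>synthVH1 synthetic germline V segment (not a natural sequence)
GGGATTTGCTCATTCCAACCATGGGCTCCTTTCATATGCGGTCAACCCGGGCAATCAGAG
TCCCGCTTGTCCTCTTATCCGCTTAAGAACGAGCGGTTGAGGATTGCTGACTATACTCGG
GTCGACGTAATTGCGCCGACCCGCACTTTTGTGGAAATGGTTATAGCCCCCAGCGATAGG
CGTGTTATCGCCATGTGCACTTACCCTCACGCTTGTAAAGGTTCTACTGCACTACCGCAC
CAGGGGATCCTTAGAAGCCTGTTTGGGCGTAAGTATATAATCTATTTTATTAAG
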