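>nuc-AlaAGC-1
CAAAAATCTTCGTCTGCTCATAAGAGGGCTGGGAGCGGATAAATGTGTTCGATGTAACCTGCTCAGCAATGCTCCA
>pla-ArgACG-2
GGAGCGGCACGGACCACATGCATTGTTAGAGCAACGGGCCAAGTTCACGCGGTAGCGATAGACGCGTCGCGTACCA
>mit-AsnGTT-3
TCACGGAGTACTCGCAAATGAAGGGCATTCCCTGTTTCTTCGGCAAATATATATAAGGTCGGAGGTAGAATCCCCA
>telem-1
TAGTGTAGAGAGGCCGGCGTTAAGTTTATGTCGAGAGACCCACGACGCGACGAGACCATTTACGATTGAAATC
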