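>demo_cds_synthetic | synthetic 90-codon ORF for dmsmap examples (not a natural gene)
ATGCGCAGGCAGGTTAACATGTCAAGACATGCAGCCTTGAGACATAGAGTTTCAACGTGT
GTTGACAACACTCCCTCACGGCCCTCTGGGTCCGTTGCATTGGGGTGGTTTGATAATAGT
CACCAGAATACGCGCTCTTTACTGCACTCTACCGGGACAATTCCAGTGTTTGTGCACTTA
CCACTACAGTGCGCTGAGTATTCAAGCACAGTTTGGGTCCCCTTGTACCCTCTGGATCGT
CATGGGTTGGTTAGAGTGGCCGACAAAGTGTAA
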