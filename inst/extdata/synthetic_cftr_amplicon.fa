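>synthetic_cftr_amplicon SYNTHETIC stand-in for the GRCh38 CFTR intron 9-exon 10 junction amplicon; 427 bp; fwd primer at 1-23, (TG)11T7 tract at 189-217, rev primer site at 404-427; flanking sequence is invented - only the primer sequences, the product size, and the reference tract follow published constants
CCATGTGCTTTTCAAACTAATTGCCGCACATCACGCGACGGCTCGCGGATAATTCTTCCG
TGGGACCTGCCTGCTGATGACGGTCGTATGGACAATCACAGGCAGCAACCGTTGGGTATT
CTTACAATTAAGCTTCTCGTAAGCAAGAAAGGGCCGTTAGGCCCACCACACACCCAACAC
CACAACCATGTGTGTGTGTGTGTGTGTGTGTTTTTTTAACCACAACACCAACCCACACCA
CCACACCTGGATCAGGAAGTACTGCCTGTCGGACAAAGGTGAGCTAGCAGACGCGTCACT
GAGAGCCAAACCCACGGCAGGCGCGCCCATCGCTGACAGCCTGTCGTTGACCCAACCTCA
GGCGCATCAGAGAACTGTACATTGGCTCGTTGGAAGTCCAAGGTGTAGTGCTGGAAGGTA
TTTTTGG
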