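>eGFP_AA|eGFP AA-biased eGFP biosensor CDS (all Lys/Gln/Glu codons AA-ending)
ATGGTGAGCAAAGGCGAAGAACTGTTCACCGGGGTGGTGCCCATCCTGGTCGAACTGGAC
GGCGACGTAAACGGCCACAAATTCAGCGTGTCCGGCGAAGGCGAAGGCGATGCCACCTAC
GGCAAACTGACCCTGAAATTCATCTGCACCACCGGCAAACTGCCCGTGCCCTGGCCCACC
CTCGTGACCACCCTGACCTACGGCGTGCAATGCTTCAGCCGCTACCCCGACCACATGAAA
CAACACGACTTCTTCAAATCCGCCATGCCCGAAGGCTACGTCCAAGAACGCACCATCTTC
TTCAAAGACGACGGCAACTACAAAACCCGCGCCGAAGTGAAATTCGAAGGCGACACCCTG
GTGAACCGCATCGAACTGAAAGGCATCGACTTCAAAGAAGACGGCAACATCCTGGGGCAC
AAACTGGAATACAACTACAACAGCCACAACGTCTATATCATGGCCGACAAACAAAAAAAC
GGCATCAAAGTGAACTTCAAAATCCGCCACAACATCGAAGACGGCAGCGTGCAACTCGCC
GACCACTACCAACAAAACACCCCCATCGGCGACGGCCCCGTGCTGCTGCCCGACAACCAC
TACCTGAGCACCCAATCCGCCCTGAGCAAAGACCCCAACGAAAAACGCGATCACATGGTC
CTGCTGGAATTCGTGACCGCCGCCGGGATCACTCTCGGCATGGACGAACTGTACAAATAA
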