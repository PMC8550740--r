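>synthetic_seed_orf synthetic 651-nt stop-free ORF (not a real accession)
ATGGTTGGTCAACGGGAAACTTTATTGATCCCGGGCATGCTAATTGGTGAAGGGCAGATCACAGTACAAG
CCGACGGCACGTCCCGCCGCGTTATACATAACTACTGTCACAGTCCAGCATTGGGTACTTCGCATATGCT
TAAGGACTGAACCCCTAGTACACCGATGTGGCCGGCTAGATGCGTCACTGCCGGTCGTCATGTCTTAGAA
TGTAAATCTCCACACAGTGGTTGTAGCTCAAGTTCCGACAACTGAACTGCCTCCGATAAACACAGGGTGT
GTGAAGTCTGTTCCCAACAAAGCGAGGAAACCAGATACATCTACGGACTCGATTCCAACTATGTTCACGA
ATATGTCGGTATCCTAAGCGAGGACGCTATTGACATCTTGGTGAACTGGAATCAAGTCAGACATCGCTTC
CCTGAGGATGTGACCCGCAAACCTAAGTCCTTACGTAGGAAGATTCATTTCTGTAGTCGTCACCCAATTT
TCAGAGACTGAAAGCTACGTCTTCTTAAAGCGTTGGAGCTGAACGGTGGCAGTGAATCCCATTGTCAAGA
ACCCCCCCAGCTATCCAAGGATAGAGGACTGGTGGTAGAATCCTCGCACCCGTATCTAGGGTTTGTGATA
GGCCGCACATGGTTAATTTTC
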