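>REF001 synthetic toy reference
AGAAGTCTTGGAGCGTCATGACTGGCAAGGATATCAGTTCGCTTTTTGAGTGCTAACTATCGGTATAGGGGCGATCTTAAAGTGTCTTATATTGACCTTGAGTAAAGCCGTCATAGTTTG
>REF002 synthetic toy reference
AGAAGTCTTGGAGCGTCATGACGGGCAAGGATATCAGTTGGCTATTTGAGTGCTAACTATCGGTATAGGGGCGATCTTAAAGTGTCTTATAGTGACCTTGAGTAAAGCCGCCATCGTTTG
>REF003 synthetic toy reference
AGTAGTCGTGGAACTTATTGACTCACAAGGAAGTCTATTTGCTTTTCCAGTGCTAGCTATCGGTGTAGCGGCGGTCAGAGAGTGTGTTAAATAGATCTTGAGTAAGGACTTCATAGATTG
>REF004 synthetic toy reference
TGAAGTATCGGAGCGGTATTAGCGGTAAGACAATCTCATTGCTGTTTGAGTGCTCGCTTTCGATTTGGAGGAGATCATGAAGTGTCATATATTGACCAGGAGTCAGCCCTTTATAGTTTG
>REF005 synthetic toy reference
AAAGGCTCAGATCGCCCGCCAAGCCACCTGTTACTCTGAATCAACGGAGTAATGAGACTTTGATCGACGGTCGACCCTTGTTATACAGTCTCACTATTTCAGCTAAAGGTCTGATACGTT
>REF006 synthetic toy reference
AGAAGACTTGGAGCGTCATGACTGGACAGGATATCAGTTCGCTTTTTGAGTGCTAACTACCGGTATAGTGGCGATCTTAAAGTGTCTTATATTGACCTTGAGTAAAGCCGTCATAGTGTG
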