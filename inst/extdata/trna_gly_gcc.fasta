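>Methanococcus_maripaludis tRNA-Gly(GCC)
GCGGCTTTGATGTAGACTGGTATCATACGGCCCTGCCACGGCCGACACCCGGGTTCAAAT
CCCGGAGGCCGCA
>Methanococcus_vannielii tRNA-Gly(GCC)
GCGGCTTTGATGTAGACTGGTATCATACGGCCCTGCCACGGCCGACACCCGGGTTCAAAT
CCCGGAGGCCGCA
>Methanococcus_voltae tRNA-Gly(GCC)
GCGGCCTTGATGTAGTGGTATCATACGGCCCTGCCACGGCCGATACCCGGGTTCAAATCC
CGGAGGCCGCA
>Methanocaldococcus_jannaschii tRNA-Gly(GCC)
GCGGCCTTGGTGTAGCCTGGTAACACACGGGCCTGCCACGCCCGGACCCCGGGTTCAAAT
CCCGGAGGCCGCA
>Halorhabdus_utahensis tRNA-Gly(GCC)
GCGACGGTGGTGTAGTGGTATCACAGGACCCTGCCACGGTCCTAACCCGAGTTCAAATCT
CGGCCGTCGCA
>Petromyzon_marinus tRNA-Gly(GCC)
GCATCGGTGGTTCAGTGGTAGAAATCTCGCCTGCCACGCGGGAGGCCCGGGTTCAATTCC
CGGCCGATGCA
>Danio_rerio tRNA-Gly(GCC)
ACATTGGTGGTTCAGTGGTAGATTTCTCGCCTGCCACGTGGGAGGCCCGGGTTCAATTCC
CGGCCAATGCA
>Strongylocentrotus_purpuratus tRNA-Gly(GCC)
GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACGCGGGGGACCCGGGTTCAATTCC
CGGCCAATGCA
>Loxodonta_africana tRNA-Gly(GCC)
GCATTGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACGTGGGAGGCCTGGGTTCAATTCC
CAGCCAGTTCT
>Callithrix_jacchus tRNA-Gly(GCC)
GCATGGGTGGTTCAGTGGTAGAATTCTCGCCTGCCACGCGGGAGTCCTGGGTTCAATCCC
CGGCCCACGCA
>Arabidopsis_thaliana tRNA-Gly(GCC)
GCACCAGTGGTCTAGTGGTAGAATAGTACCCTGCCACGGTACAGACCCGGGTTCAATTCC
CGGCTGGTGCA
>Medicago_truncatula tRNA-Gly(GCC)
GCACCAGTGGTCTAGTGGTAGAATAGTACCCTGCCACGCTACAGACCCGGGTTCAATTCC
TGGCTGGTGCA
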