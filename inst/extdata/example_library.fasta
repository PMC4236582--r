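>ISceI role=isceI_site name=ISceI notes=canonical_18_bp_I-SceI_recognition_site_(external-knowledge_default)
TAGGGATAACAGGGTAAT
>BBa_B1006 role=terminator name=BBa_B1006 notes=synthetic_placeholder_terminator_(provisional;_supply_real_part)
CCGGCCGCGTTCGCGCGGCCGGTTTTTTTT
>BBa_B1002 role=terminator name=BBa_B1002 notes=synthetic_placeholder_terminator_(provisional;_supply_real_part)
GGGGCGACTTCGGTCGCCCCTTTTTTTT
>BBa_K259002 role=spacer name=BBa_K259002 notes=synthetic_placeholder_spacer_(provisional)
AATTAATAATTTCCCAATTTAGTGTCCCTC
>BBa_B0040 role=spacer name=BBa_B0040 notes=synthetic_placeholder_spacer_(provisional)
TGGCGATACTGTTACAGATGCCTA
>cat role=marker name=cat notes=synthetic_placeholder_chloramphenicol-resistance_ORF_(660_bp)
ATGCTGACCCTACCTACTGAAGGCGCGTTCTCCGAAAGGCGACCCGGGAAGCAGAAGCTCCTTCGGTATG
GGGGAGTTAGTGCCTCTGGAATAGGCCATGTCAGTGGCGAGCGCGATAATTCAGATCAGCGTGAACCCTC
GGCAGTCGCAACTGTCTCGAACCTAAGCTTGGGGTGCAGCCAGCTCTACAAGACCGGAGGGCTCCAGCCG
CAGTTCAGGATCAGCCGATCGTGCGGAGGTTTATGTCGAGTCAATGAATGTAGGAGGCCCCTTTACGTTG
TCATCCGCGGTCGAAATATTTTTAGCCACAACTACCTAGTTCGAGAAGACTTAATAACTCTTGAGACACT
AGTGAGGGCCGAATCTCACTACCTGTGTTCGGTTTGGCTGTGTTCCGGGTCATTAAATGCCAATCTGCGT
GATGTTCGGGGTACTAAGTCAGCCCGCACCCGTGCGGTCTGGATACTGGTGTCCTCGCTGGACTGTGAAC
AGTCTTGGTATAAGGAGCCTACCTCCTCCGGTCGGTTGTGCCCCTTTCGGTCCTTCCTACATCTCAGCCT
ACGCCTAAAAGTAGATAGCCACGGATTACAAGCATCACGGTTCTATCGGCCGCAGAGTCAGACATGGGCC
GTTCGAGTGCGCATTCCCGCGTTTTTTTAA
>kan role=marker name=kan notes=synthetic_placeholder_kanamycin-resistance_ORF_(816_bp)
ATGTCTGTCCAACATACGCAGCGTAATTCTCACCGGAACCACGGCTCCATACCCCCTAGTAGAGTCACCC
GAATTCTTGTGTTATATACTTGCGAGGTTGTGGCTCCTGCCTTTCACCTATCGAAGTACCAACATGAATC
ACCCGAGATCGTACGGAGTAAAACTGCCGCCACGACGGTCCAAGGAGTTGACCCTTTCCGGGTACTCGGT
GACCTGGCAGAAGATTGGCACGACCGTTGGAAAGAACTCCTAGGGATTAGCGGTCCGCAGATTTGTACGC
TGGCGCAAGTCGAAGGAACTCCAAGGATCGAGCATGGCCTGGGAAAAAACCCAGAAAGGTGTGGTATTGT
CAAAGGAGACCGGTTCGTAACACGACCTTCTCATGTACCTCTCCTACGTAGGCAAGTTAACCAAGGCTTA
CCATCTGGGCTATTCACGGAGCTTACAATTCTGTGCCGTGACGGTTGTAACACCGAGTGGGGTCGTGCGC
ACAGCGATAGGAGGTACAGGTTAGGATACTCTTACCAGCCGGGACGGCTGCTTCGACACATACCGCACAT
AATAGGTACGTTCCCGCTATGTGCCCGACGAGAAAGAGCGGGAAAGGCGCTGCCCCGCCGCTTCCCGTGC
CGGGCCAATGCAGACTCCATTGCGAGTGACAAAACAGGGAAACCGCGCGCTGTGACCGTACTCCGACCCG
TATTTAGCTCTAGAAATACTACCACTACCGGTAGAAAGTGGTGTAACATAGAGCCGTTGTGGACGGGATC
CAGATTAAACTTTATCTTAGCTGATTGTGTTGACGGATCAAGGTAA
>dfrA role=marker name=dfrA notes=synthetic_placeholder_trimethoprim-resistance_ORF_(495_bp)
ATGGTGAGAACCACAGACCCTTTATGGTTAGCAGACGAGGACAAGACACGCGCATTAGGGAAGGCGTTGA
ATCTGGTTTTCCATACTTCAGCCTGCCTGGACTGGCCTGGCGGAGCTGTTCTTCTCGGAATATTTGTCAC
GGTGCCATTTCTCAGATCTACTTGCGTAGGGTGTCTTTCAGTACGGGGTGAAGGGCGGGCGCTAGGGTCT
CCGTCCAGGGAGGACTATGATGCATTTGCACGATGGTGCGCGATAACGAAGCATGTTCTTGCGCCCCCAC
GAGCCGTTAATAGACTCTCAAGAGAGAGTCAGTTCGGGGTCGAGGTACCGCTGCGCGCTCTCTGCGGCGG
GTCCAAGGCGGCAGTCCCAGGCCCCCCTCTCTCGGCCTTGCTGGATGTTTGCCTACTGGTAATAGCGTTT
CTTACACCGGACGCTATCCCGCCGTTGACGCCATTGGCTACGTACGTCAGCCCTCACGGCGACGCCGTAA
GTTAA
>Pconst role=promoter name=Pconst notes=synthetic_placeholder_constitutive_promoter
TTTGTATATTCTGCGTCTTAAGCATGACAACCGTTATGTTAAGTAGGAACGAGCGATTGT
>FLAG3x role=tag name=FLAG3x notes=3xFLAG_tag,_standard_peptide,_fixed_synthetic_codon_choice
GACTACAAAGACCATGACGGTGATTATAAAGATCATGACATCGATTACAAGGATGACGATGACAAG
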