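>NDUFA12_like|outgroup|A
CATTCAAATGAGGGTCCTTATGAGTCCTACATTTTCACCATTAGGGTTCAGAGCTCTTCTCATGGGCTATTAGTTTGGGT
GGCCATTTCTACTCCATACTTGGGAATCCGGGCACCGAGGACGATAATGATAACCGAGAACACGGCTTTTACCTTAAGCA
GGGTACTCTGTTTGAGCGAGCCTAATTCACCGTACCGCGTTCATTTACGCCCCCACTGTCTCTGTAGGAGTTGTAGACCA
GCATGGACAGCCAGGGACCTATGGGGTTGTCGTGAGGGGGAATTACCTGATCAATGGCTTTTAACCGTCAATCTGCACGG
ACAACCCATCCCATTGCCCACAATTATACAGACTGCTGTAACTCATCTGCACCTGCGGCACAGCAGGCGTCAAGACATCA
CCGGCGCTGATCCATATCTCCGTATAGTCGGTCCCCCGGGC
>NDUFA12_like|coastal|A
CATTCAAATGAGGGTCCTTATGAGTCCTACATTTTCACCATTAGGGTTCAGAGCTCTTCTCATGGGCTATTAGTTTGGGT
GGCCATTTCCACGCCATACTTGGGAATCCGGGCACCGAGGACGATAATGATAACCGAGAACACGGCTTTTACCTTAAGCA
GGGTACTCTGCTTGAGCGAGCCTAATTCACCGTACCGCGTTCATTTACGCCCCCACTGTCTCTCTAGGGGTTGTAGACCA
GCATGGACAGCCAAAGACCTATGGGGTTGTCGAGAGGGGGAATTACCTGATCAATGGCTTTTAACCGTCAATCTGCACGG
ACAACCCATCCCATTGCCCACAATTATTAAGACTGCTGTAACTCATCTGCACCTGCGGCACAGCAGGCGTCAAGACATCA
CCGACGCTGATCCATATCTCCGTATAGTCGGTCCCCCGGGC
>NDUFA12_like|coastal|Z
CATTCAAATGAGGGTCCTTATGAGTCCTACATTTTCACCATTAGGGTTCAGAGCTCTTCTCATGGGCTATTAGTTTGGGT
GGCCATTTCCACGCCATACTTGGGAATCCGGGCACCGAGGACGATAATGATAACCGAGAACACGGCTTTTACCTTAAGCA
GGGTACTCTGCTTGAGC------------------------------------------------AGGGGTTGTAGACCA
GCATGGACAGCCAAAGACCTATGGGGTTGTCGAGAGGGGGAATTACCTGATCAATGGCTTTTAACCGTCAATCTGCACGG
ACAACCCATCCCATTGCCCACAATTATTAAGACTGCTGTAACTCATCTGCACCTGCGGCACAGCAGGCGTCAAGACATCA
CCGACGCTGATCCATATCTCCGTATAGTCGGTCCCCCGGGC
>NDUFA12_like|coastal|W
CATTCAAATGAGGGTCCTTATGAGTCCTACATTTTCACCATTAGGGTTCAGAGCTCTTCTCATGGGCTATTAGTTTGGGT
GGCCATTTCCACGCCATACTTGGGAATCCGGGCACCGAGGACGATAATGATAACCGAGAACACGGCTTTTACCTTAAGCA
GGGTACTCTGCTTGAGCGAGCCTAATTCACCGTACCGCGTTCATTTACGCCCCCACTGTCTCTCTAGGGGTTGTAGACCA
GCATGGACAGCCAAAGACCTATGGGGTTGTCAAGAGGGGGAATTACCTGATCAATGGCTTTTAACCGTCAATCTGCACGG
ACAACCCATCCCATTGCCCACAATTATTAAGACTGCTGTAACTCATCTGCACCTGCGGCACAGCAGGCGTCATGACATCA
CCGACGCTGATCCATATCTCCGTATAGTCGGTCCCCCGGGC
>NDUFA12_like|inland|A
CATTCAAATGAGGGTCCTTATGAGTCCTACATTTTCACCATTAGGGTTCAGAGCTCTTCTCATGGGCTATTAGTTTGGGT
GGCCATTTCCACGCCATACTTGGGAATCCGGGCACCGAGGACGATAATGATAACCGAGAACACGGCTTTTACCTTAAGCA
GGGTACTCTGCTTGAGCGAGCCTAATTCACCGTACCGCGTTCATTTACGCCCCCACTGTCTCTCTAGGGGTTGTAGACCA
GCATGGACAGCCAAAGACCTATGGGGTTGTCGAGAGGGGGAATTACCTGATCAATGGCTTTTAACCGTCAATCTGCACGG
ACAACCCATCCCATTGCCCACAATTATTAAGACTGCTGTAACTCATCTGCACCTGCGGCACAGCAGGCGTCAAGACATCA
CCGACGCTGATCCATATCTCCGTATAGTCGATCCCCCGGGC
>NDUFA12_like|inland|Z
CATTCAAATGAGGGTCCTTATGAGTCCTACATTTTCACCATTAGGGTTCAGAGCTCTTCTCATGGGCTATTAGTTTGGGT
GGCCATTTCCACGCCATACTTGGGAATCCGGGCACCGAGGACGATAATGATAACCGAGAACACGGCTTTTACCTTAAGCA
GGGTACTCTGCTTGAGC------------------------------------------------AGGGGTTGTAGACCA
GCATGGACAGCCAAAGACCTATGGGGTTGTCGAGAGGGGGAATTACCTGATCAATGGCTTTTAACCGTCAATCTGCACGG
ACAACCCATCCCATTGCCCACAATTATTAAGACTGCTGTAACTCATCTGCACCTGCGGCACAGCAGGCGTCAAGACATCA
CCGACGCTGATCCATATCTCCGTATAGTCGATCCCCCGGGC
>NDUFA12_like|inland|W
CATTCAAATGAGGGTCCTTATGAGTCCTACATTTTCACCATTAGGGTTCAGAGCTCTTCTCATGGGCTATTAGTTTGGGT
GGCCATTTCCACGCCATACTTGGGAATCCGGGCACCGAGGACGATAATGATAACCGAGAACACGGCTTTTGCCTTAAGCA
GGGTACTC------------------------------------------------------------------------
--------------------------------------------------------------------------------
--------------------------------------------------------------------------------
-----------------------------------------
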