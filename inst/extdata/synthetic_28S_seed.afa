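>syn28S_01
GGACAATGACCGCCCTAGTGATGGGTCTTCCCTCATCAGAAAACTTATTTGGTAAGTGAGACCTGAATTTCGGGT-TCCCT
>syn28S_02
GGCCAATGACGGCCCTAGTGATGGGTCTTCCCCCATCAGAAAACTTTTTTGGTAAGTGAGACCTGAATTTCGGGTATCCCT
>syn28S_03
GGCCAATGACCGCGCTAGTG-TGGGTCTTCCCCCATCAGAACACTTATTTGGTAAGTGAGACCTGAATTTCGGGT-TCCCT
>syn28S_04
GGCCAATGACCGCCTTAGTGATGGGTCTTCCCCCATCAGAAAACTTATTTGGTAAGTGAGACCTGATTTTCGGGT-TCCCT
>syn28S_05
GGCCAATGACCGCCCTTCTGATGGGTCTTCCCCCATCAGAAAACTTATTTGGTAAGTGAGACCTGAATTTCGGGTGTCCCT
>syn28S_06
GGCCAATCACCGCCCTAGTGATGGGTCTTCCCCCATCAGAAAACTTATTTGGTAAGTGAGACCTCAATTTCGGGT-TCCCT
>syn28S_07
GGCCAATGGCCGCCCTAGTGATGGGTCTTCCCCCATCAGAAAACTTATTTGGTAAGTGAGACCTGAATTTCGGGT-TCTCT
>syn28S_08
GGCCAATGACCGCACTAGTGATGGGTCTTCCCCCATCAGAAAAATTATTTGGTAAGTGAGACCTGAATTTCGGGT-TCCCT
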