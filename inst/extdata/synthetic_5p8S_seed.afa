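>syn5p8S_01
ACATGCATTCTAGGAAGCGCAATC-ATAGTCTGACCTAGATCAGCTCTCGTGACAGTAGTG
>syn5p8S_02
ACATGTATTCTAGGAAGCGCAATCGATAATCTGACCTCGATCAGCTCTAGTGACAGTAGTG
>syn5p8S_03
ACATGCATTCTAGGAACCGCAATC-ATAGTCTGACCTCGATCAGC-CTAGTGACCGTAGTG
>syn5p8S_04
ACATGCATTCTAGGAAGCGCAATC-ATATTCTGACCTCGATGAGCTCTAGTGACAGTAGTG
>syn5p8S_05
ACATGCATTCTCGGAAGCGCAATCCATAGTCTGCCCTCGATCAGCTCTAGTGACAGTAGTG
>syn5p8S_06
ACAAGCATTCTAGGAAGCGCAATC-ATAGTCTGACCTCGATCAGCTCTAGTGAAAGTAGTG
>syn5p8S_07
ACATACATTCTATGAAGCGCAATC-ATAGTCTGACCTCGATCAGCTCTAGTGACAGTAGTG
>syn5p8S_08
ACATGCATTCTAAGAAGCGCAATC-ATAGTCTGACCGCGATCAGCTCTAGTGACAGTAGTG
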