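>outgroup
CTAGGCTACGCCTGCCGCACCACGGGGCGGGGCTGCATAGTCCGCGTGTCCCACCTCACG
CCGAAATTCAAACTAGAGCCGGCGACTCTGCCGGCGGAGGAGTTCGTACAACGCGCGCGC
CTCTTTTCGCAGAGTACCGTAGACAGCTATCGAATCATTCCGATCTCCGGAGAGTTGAAG
GAGCAGTCGCTCTCTAACCGCGCGACCAGGAAGAGCGCTCCACTCAGGAGGCGGCCGAAC
CATAGATACTCGTTCGTGGTC
>g1_sp1
CTGGGTTACGACTGCCAGCCAACCGGGCGCGGGTGCATTGTCCGCGTGTCGCACCTAACG
CCGAAGTTCAAGCTAGATCCCGCGACTCTTCCCGCCGAGGAGTTCGTGCAACGGGCGCGC
ACGTTCTCGCGGAGCACGGTCGACAGTTACAGGATCATTCCGATAATCGGAGAGTTGAAG
GGGCAATCGCTGTCGAACCGTGCGACCCGGAAGAGCGCTCCGCTCAGGCGCCTGCCGAAT
CATAGATGCTCCTTCGTCGTC
>g1_sp2
CTGGGTTACGACTGCCAGCCAACCGGGCGCGGGTGCATTGTCCGCGTGTCGCACCTAACG
CCGAAGTTCAAGCTAGATCCCGCGACTCTGCCCGCCGAGGAGTTCGTGCAACGGGCGCGC
ATGTTCTCGCGGAGCACGGTCGACAGTTACAGGATCATTCCGATAATCGGAGAGTTGAAG
GGGCAATCGCTGTCGAACCGCGCGACCCGGAGGAGCGCTCCGCTCAGGCGCCTGCCGAAT
CATAGATGCTCCTTCGTCGTC
>g1_sp3
CTGGGTTACGACTGCCAACCAACCGGGCGCGGGTGCATTGTCCGCGTGTCGCACCTAACG
CCGAAGTTCAAGCTAGATCCCGCGACTCTGCCCGCCGAGGAGTTCGTGCAACGGGCGCGC
ATGTTCTCGCGGAGCACGGTCGACAGTTACAGGATCATTCCGATAATCGGAGAGTTGAAG
GGGCAGTCGCTGTCGAACCGCGCAACCCGGAGGAGCGCTCCGCTGAGGCGCCTGCCGAAT
CATAGATGCTCCTTCGTCGTC
>g1_sp4
CTGGGTCACGACTGCCAACCCACCGGGCGCGGGTGCATTGTCCGCGTGTCGCACCTGACG
CCGAAGTTCAAGCTAGATCCCGCGACTCTGCCCGCCGAGGAGTTCGTGCAACGGGCGCGC
ATGTTCTCGCGGAGCACGGTCGACAGTTACAGGATCATTCCGATATTCGGAAAGTTGAAG
GGGCAATCGCTGTCTAACCGCGCGACCCGGAAGAGCGCTCCATTGAGGCGCCTGCCGAAT
CATAGATGCTCCTTCGTCGTC
>g1_sp5
CTGGGCTACGATTGCCAACCCACCGGGCGCGGGTGCATTGTCCGCGTGTCGCACCTAACG
CCGAAGTTCAAGCTAGATCCCGCGACTCTGCCCGCCGAGGAGTTCGTGCAACGGGCGCGC
ATGTTCTCGCGAAGCACGGTGGACAGTTACAGGATCATTCCGATATTCGGAGAGTTGAAG
GGGCAATCGCTGTCTAACCGCGCGACCCGGAAGAGCGCTCCGTTGAGGCGCCTGCCGAAT
CATAGATGCTCGTTCGGCGTC
>g1_sp6
CGGGGCTACGATTGCCAACCAACCGGGCGCGGGTGCATTGTCCGCTTGTCGCACCTAACG
CCGAAGTTCAAACTTGATCCCGCGACTCTGCCCGCGGAGGAGTTCGTACAACGGGCGCGC
ATGTTCTCGCGAAGCACGGTCGACAGCTACAGGATCATCCCGATATTCGGGGAGTTGAAG
GGGCAATCGCTGTCTAACCGCGCGACCCGGAAGAGCGCCCCGTTGAGGCGCCTACCGAAT
CATAGATGCTCGTTCGTCGTG
>g1_sp7
CTGGGTTACGATTGCCAACCCACCGGGCGCGGGTGCATTGTTCGGGTGTCCCACCTAACG
CCGAAGTTTAAACTAGATCCCGCGACTCTGCCCGCCGAGGAGTTCGTACAACGGGCGCGC
CTGTTCTCGCGCAGCACGGTCGACAGTTACAGGATCATTCCGGTGTCCGGGGAGTTAAAG
GGGCAATCGCTGTCTAACCGCGCGACCCGGAAGAGCGCTCCGTTGAAGCGCCTGCCGAAT
CATAGGTGCTCGTACGTCGTC
>g5_sp1
CTGGGCTACGATTGCCGGACCACAGGGCGGGGATGCATTGTCCGCGTCTCCCACCTAACG
CCGAAGTTCAAACTGGACCCCGCGACCTTGCCCGCAGAGGAGTTCGTACAGCGGGCACGC
CTGTTCTCACGCAGCACGGTCGACAGTTATAGGATCATCCCGATCTTCGGCGAATTCAAG
GAGCAGTCGTTGTCCAACCGCGCGACCCGGAAGAGCGCTCCCCTGAGGCGCCTGCCGAAT
CATAGATGCTCGTTCGTCGTC
>g5_sp2
CTGGGCTACGATTGCAGGACTGCAGGGCGGGGGTGCATTGTCCGGGTCTCCCACCTAACG
CCGAAGTTCAAACTGGACCCCGCGACCTTGCCCGCAGAGGAGTTCGTACAGCGGGCACGT
CTGTTCTCACGCAGCACGGTCGACAGTTATAGGATCATCCCGATCTTCGGCGAATTCAAG
GAGCAGTCGCTGTCCAACCGTGCGACCCGGAAGAGCGCTCCGCTGAGGCGCCTGCCGAAT
CATAGATGCTCGTTCGTCGTG
>g5_sp3
CTGGGCTACGATTGCCGGACTACAGGGCGGGGGTGCATTGTCCGCGTCTCCCACCTAACG
CCGAAGTTCAAACTGGACCCCGCGACCTTGCCGGCAGAGGAGTTCGTACAGCGGGCACGC
CTGTTCTCGCGCAGCACGGTCGACAGTTATAGGATCATCCCCATCTTCGGCGAATTCAAG
GAGCAGTGGTTGTCCAACCGCGCGACCCGGAAGAGCGCCCCGCTGAGGCGCCTGCCGAAT
CATAGATGCTCGTTCGTCGTC
>g5_sp4
TTGGGCTACGATTGCCGGACTACAGGGCGGGGGTGCATTGTCCGCGTCTCCCACCTAACC
CCGAAGTTCAAACTGGACCCCGCGACCTTGCCCGCAGAGGAGTTCGTACAGCGGGCACGC
TTGTTCGCGCGCAGCACGGTCGACAGTTATAGGATCATCCCGATCTTCGGCGAATTCGAG
GAGCAGTCGTTGTCCAACCGCGCGACCCGGAAGAGCGCTCCGCTGAGGCGCCTGCCGAAT
CATAGGTGCTCGTTCGTCGTC
>g5_sp5
TTGGGCTACGACTGCCGAACTACAGGGCGGGGGTGCATCGTCCGAGTCTCCCACCTAACG
CCGAAGTTTAAACTGGACCCCGCGACCTTGCCCGCAGAGGAGTTCGTACAGCGGGCACGC
CTGTTCTCACGCAGCACGGTTGACAGTTATAGGATTATTCCGATCTTCGGCGAATTCAAG
GAGCAGTCGTTGTCCAACCGCGCGACCCGGAAGAGCGCTCCGTTGCGGCGCTTGCCGAAT
CATAGATGCTCGTTCGTCGTC
>g5_sp6
CTGGGCTACGCTTGCCGAACTACTGGGCGGGGGTGCATTGTACGCGTCTCCCACCTAACG
CCGAAGTTCAAACTAGACCCCGCGACCTTGCCCGCAGAGGAGTTCGTACAGCGGGCCCGC
CTGTTCTCGCGCAGCACGGTCGACAGTTATAGGATCATCCCGATCTTCGGCGAATTCAAG
GAGCAATCGTTGTCCAACCGCGCGACCCGGAAGAGCGCGCCCCTGAGGCGGCTGCCAAAT
CATAGATGCTCGTTCGTCGTC
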