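>barcode01
GCATCGACTTTAGTGCAAGAATAA
>barcode02
TGGACGCGTAGTCTCCACTGACAA
>barcode03
AATGGCTCGGGGCGGCAATTCTGC
>barcode04
GCCGACATTTTACCGCGGTAAAAC
>barcode05
ACTCATAGTGCGTGTACGCTCCCG
>barcode06
CCCTTTACTATCAGCACCGTCTGC
>barcode07
TTTCATAGCAGCAGGATAGTTTCC
>barcode08
ATGCTAATCGTAGAAAGTTCGTTC
>barcode09
TCGACAGTTGGCGTGTCCGGGTTA
>barcode10
TATGTATCACGGGTATATATCTAA
>barcode11
TATCATAGTCCCACGCTTTGGGCT
>barcode12
CAGCACCTCTCGTGGAGCAGGCCC
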