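>W
TTCGGGATGTTAGTACCA
>R
ATATTTTTCACGGCACCA
>F
GACAGTGTTCAACTGCCA
>I
TCGGTTTGGAGCCCACCA
>S
GCACCAGCCCAACCGCCA
>P
CCGCCTGTCGCGTGTCCA
>L
CTACGGAGTGCATCTCCA
>N
TGGAGACAAACTAGACCA
>E
TCCCCGATACTGGGTCCA
>G
CCCGTGCTTAGGTATCCA
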