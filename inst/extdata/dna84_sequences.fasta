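>strand_1 84-base conjugate strand (5'-thiol)
CCGGCGGCCCAGGTGTATCAGTGTTCGTTGCAAGCTCCAACATCTGAGTACCACGCATAC
TATACTTGAAATATCCGCGCCCGG
>strand_2 84-base complement strand (5'-thiol)
CCGGGCGCGGATATTTCAAGTATAGTATGCGTGGTACTCAGATGTTGGAGCTTGCAACGA
ACACTGATACACCTGGGCCGCCGG
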