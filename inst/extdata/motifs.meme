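MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF gbox_core bZIP
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
0.970000  0.010000  0.010000  0.010000
0.010000  0.970000  0.010000  0.010000
0.050000  0.050000  0.850000  0.050000
0.010000  0.010000  0.010000  0.970000
0.050000  0.050000  0.850000  0.050000
0.100000  0.200000  0.600000  0.100000

MOTIF abre_like bZIP
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
0.900000  0.033000  0.033000  0.034000
0.033000  0.900000  0.033000  0.034000
0.033000  0.033000  0.900000  0.034000
0.033000  0.033000  0.034000  0.900000
0.033000  0.033000  0.900000  0.034000
0.100000  0.100000  0.700000  0.100000
0.100000  0.700000  0.100000  0.100000

MOTIF myb_core MYB_related
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
0.050000  0.050000  0.050000  0.850000
0.850000  0.050000  0.050000  0.050000
0.850000  0.050000  0.050000  0.050000
0.050000  0.800000  0.100000  0.050000
0.100000  0.100000  0.700000  0.100000
0.050000  0.050000  0.050000  0.850000

MOTIF gata_box GATA
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
0.400000  0.100000  0.100000  0.400000
0.050000  0.050000  0.850000  0.050000
0.900000  0.033000  0.033000  0.034000
0.050000  0.050000  0.050000  0.850000
0.900000  0.033000  0.033000  0.034000
0.450000  0.050000  0.450000  0.050000

MOTIF wbox_core WRKY
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
0.050000  0.050000  0.050000  0.850000
0.050000  0.050000  0.050000  0.850000
0.050000  0.050000  0.850000  0.050000
0.900000  0.033000  0.033000  0.034000
0.050000  0.850000  0.050000  0.050000
0.200000  0.500000  0.100000  0.200000
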