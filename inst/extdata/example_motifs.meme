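MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.29 C 0.21 G 0.21 T 0.29

MOTIF gata_like
letter-probability matrix: alength= 4 w= 6 nsites= 40 E= 0
 0.050 0.050 0.850 0.050
 0.850 0.050 0.050 0.050
 0.050 0.050 0.050 0.850
 0.850 0.050 0.050 0.050
 0.700 0.100 0.100 0.100
 0.100 0.100 0.700 0.100

MOTIF grh_like
letter-probability matrix: alength= 4 w= 8 nsites= 30 E= 0
 0.700 0.100 0.100 0.100
 0.100 0.700 0.100 0.100
 0.050 0.050 0.050 0.850
 0.050 0.050 0.050 0.850
 0.100 0.100 0.700 0.100
 0.050 0.050 0.050 0.850
 0.050 0.050 0.050 0.850
 0.100 0.700 0.100 0.100

MOTIF zld_like
letter-probability matrix: alength= 4 w= 7 nsites= 25 E= 0
 0.100 0.700 0.100 0.100
 0.850 0.050 0.050 0.050
 0.100 0.100 0.700 0.100
 0.100 0.100 0.700 0.100
 0.050 0.050 0.050 0.850
 0.850 0.050 0.050 0.050
 0.250 0.250 0.250 0.250

MOTIF bcd_like
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.050 0.050 0.050 0.850
 0.850 0.050 0.050 0.050
 0.850 0.050 0.050 0.050
 0.050 0.050 0.050 0.850
 0.100 0.700 0.100 0.100
 0.100 0.700 0.100 0.100
 0.250 0.250 0.250 0.250
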