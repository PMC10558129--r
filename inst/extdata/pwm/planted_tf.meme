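MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.35 C 0.15 G 0.15 T 0.35

MOTIF planted_tf synthetic tissue transcription factor (fixture)
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.850000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.050000 0.850000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.850000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
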