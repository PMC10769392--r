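# Example MEME-like probability matrices (synthetic motifs)
MOTIF synthetic_activator
letter-probability matrix: alength= 4 w= 8
0.94 0.02 0.02 0.02
0.02 0.94 0.02 0.02
0.02 0.02 0.94 0.02
0.02 0.02 0.02 0.94
0.94 0.02 0.02 0.02
0.45 0.35 0.10 0.10
0.02 0.02 0.94 0.02
0.02 0.94 0.02 0.02

MOTIF synthetic_repressor
letter-probability matrix: alength= 4 w= 6
0.02 0.02 0.94 0.02
0.02 0.02 0.94 0.02
0.02 0.94 0.02 0.02
0.02 0.94 0.02 0.02
0.10 0.45 0.35 0.10
0.02 0.02 0.02 0.94
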