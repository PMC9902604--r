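>ctcf_synthetic synthetic consensus-style CTCF matrix (19 positions, counts per 100); user-replaceable default, not derived from any database entry
A [  9  5 70  8  6 72  7  6 10  8  7  9  6  8  9 60  8 12 10 ]
C [ 70 78 12 62 75  9  8  7 11  9  8 68 10 66 12 14 10 10 12 ]
G [ 12  9  8 20  9  9 74 77 15 70 75 11 72  9 13 16 70 14 62 ]
T [  9  8 10 10 10 10 11 10 64 13 10 12 12 17 66 10 12 64 16 ]
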