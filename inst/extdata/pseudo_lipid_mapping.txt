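; 11-particle pseudo-lipid -> 5 beads (head + 2 beads per tail)
; matches the particle naming of make_pseudo_lipid(3, 4, 2)
[atoms]
N1 N2 N3
C1A C2A C3A C4A
C1B C2B C3B C4B
HEAD: N1 N2 N3
T1A: C1A C2A
T2A: C3A C4A
T1B: C1B C2B
T2B: C3B C4B
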