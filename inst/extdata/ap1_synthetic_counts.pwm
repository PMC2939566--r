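>AP1_synthetic_counts (synthetic example matrix matching the TGASTCA consensus; not the published AP1 matrix)
A  0  0 20  0  0  0 20
C  0  0  0 10  0 20  0
G  0 20  0 10  0  0  0
T 20  0  0  0 20  0  0
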