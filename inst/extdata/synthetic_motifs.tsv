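# Synthetic repeat-unit catalog: five 60-nt GC-rich units emulating the
# unit length and base composition of the MUC1 coding VNTR. These are
# generated sequences, not real MUC1 motifs (no public motif inventory
# exists); chosen so that every unit's doubled string has 60 distinct
# 25-mers and merged candidate-insertion groups have disjoint
# diagnostic k-mer sets.
motif_id	sequence
u1	GGCCCCTGGCGTGATACGGAGTCCTTGCTGCTTACTTTCGCGCCCGGCGGGCGCACGGCT
u2	TGGAACGGGCTAAGTCCTCTCGCGCGAACCGATGTAGGGAGCGGTTCAGATGAGGCGGCC
u3	GGCCTCATCGAGGGTTCTGCGTGGCTAGCGCGACCACCGCGCCCCGGCGACTCTCGTGCT
u4	CCCCCCCCCATGCTTACTGGCGCGGCTCCAGGGGCACCAGCCTGCACGGGCGCCACCGCC
u5	CATCTCCTCCCGCGGCCCCCTCGCCGCCAGGACCCCCTTGAGCCCTGGGAGGCGGACGGC
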