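node	class
outgroup	pre
node16	pre
node17	stem_g1
node18	g1
node19	g1
node20	g1
node21	g1
node22	g1
g1_sp1	g1
g1_sp2	g1
g1_sp3	g1
g1_sp4	g1
g1_sp5	g1
g1_sp6	g1
g1_sp7	g1
node23	stem_g5
node24	g5
node25	g5
node26	g5
node27	g5
g5_sp1	g5
g5_sp2	g5
g5_sp3	g5
g5_sp4	g5
g5_sp5	g5
g5_sp6	g5
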