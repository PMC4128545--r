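parameter	value
k	1e-09
w	0.05
b_G	17
b_W	20
L	10
v	0.1
Z	0.1
C	5e+09
h_max	0.2
release_shape	19
release_decay	0.999997
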