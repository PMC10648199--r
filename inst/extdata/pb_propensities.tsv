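letter	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
a	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	1.0	0.2	-0.2	-0.2	-0.2
b	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	0.2	1.0	-0.2	-0.2	-0.2
c	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	1.0
d	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	1.0	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2
e	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	1.0	-0.2	-0.2	-0.2	0.2	-0.2	-0.2
f	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	0.2	1.0	-0.2
g	-0.2	-0.2	1.0	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2
h	-0.2	-0.2	0.2	1.0	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2
i	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	1.0	0.2	-0.2
j	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	1.0	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2
k	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	1.0	-0.2	-0.2	-0.2	-0.2	-0.2
l	-0.2	-0.2	-0.2	-0.2	-0.2	1.0	0.2	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2
m	1.0	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2
n	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	1.0	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2
o	-0.2	0.2	-0.2	-0.2	-0.2	0.2	-0.2	-0.2	-0.2	-0.2	-0.2	1.0	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2
p	-0.2	-0.2	-0.2	0.2	-0.2	0.2	1.0	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2	-0.2
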