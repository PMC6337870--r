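aa	atp_equivalents
A	1.0
R	13.1
N	5.6
D	2.7
C	11.2
Q	2.0
E	2.6
G	2.2
H	33.1
I	11.3
L	2.1
K	12.2
M	21.3
F	6.0
P	7.9
S	1.1
T	9.0
W	31.1
Y	8.0
V	4.2
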