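# Six-way physicochemical partition of the 20 standard amino acids used for
# the 6x6 substitution-group one-hot features (cells named g<i>_g<j>).
# g2 must be the negatively charged pair and g6 must contain A and T so that
# the published selected-feature name "g2_g6" resolves to the D/E -> A/T cell.
aa	group
I	g1
L	g1
M	g1
V	g1
D	g2
E	g2
F	g3
W	g3
Y	g3
N	g4
Q	g4
S	g4
C	g4
H	g5
K	g5
R	g5
A	g6
G	g6
P	g6
T	g6
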