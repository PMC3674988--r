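# Default side-chain pharmacophore feature assignment.
# Format: one amino acid per line, "CODE: feature,feature,..."
# Features: L lipophilic, R aromatic, A acceptor, D donor, P positive,
# N negative. An empty right-hand side means no side-chain feature.
A: L
R: D,P
N: A,D
D: A,N
C: L
Q: A,D
E: A,N
G:
H: R,A,D,P
I: L
L: L
K: D,P
M: L
F: L,R
P: L
S: A,D
T: A,D
W: L,R,D
Y: R,A,D
V: L
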