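# Synthetic 7-node toy network (A..G).
# This is NOT a published rule set: it is a reconstruction searched for
# computationally so that it reproduces every printed fact of the 7-node
# worked example used to illustrate boundary-reaching control:
#   - (A,B,C,D,E,F,G) = (1,0,1,1,1,1,0) is a fixed-point attractor (beta)
#   - peeling removes G, then F; the core is {A,B,C,D,E}
#   - C is deterministic via the indegree-1 nodes B and E; B, D, E are
#     nondeterministic with a deterministic input
#   - the reduced basin of beta has C fixed at 1 and A,B,D,E unfixed
#   - (0,0,1,0,0,0,0) is a terminal basin state on a trajectory to beta
#   - alpha = (0,0,0,0,1,0,0) has mHD 1, unique boundary state
#     (0,0,1,0,1,0,0) and minimum control target set {C -> 1}
targets, factors
A, (!B & E) | (B & !C & !E)
B, !C
C, (!D & (!A | B)) | (A & !B & D)
D, (B & !(C & E)) | (!B & C & E)
E, C
F, E
G, !F
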