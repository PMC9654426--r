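pair,bond,atom_a,atom_b,mean,sd
A13:T18,HB1,N6,O4,3.04,0.22
A13:T18,HB2,N1,N3,2.95,0.11
A13:T18,CO..H,C2,O2,3.59,0.26
C7:G24,HB1,N1,N3,2.96,0.10
C7:G24,HB2,O6,N4,2.90,0.13
C7:G24,HB3,O2,N2,2.88,0.13
G8:T23,HB1,O4,N1,3.03,0.18
G8:T23,HB2,O4,N2,2.87,0.11
G8:T23,CO..H,C7,O6,3.47,0.29
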