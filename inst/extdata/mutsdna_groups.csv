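pair,bond,mean,sd
A13:T18,HB1,-3.7,1.2
A13:T18,HB2,-4.3,0.6
A13:T18,CO..H,-0.8,0.4
A13:T18,rest,0.0,0.5
A13:T18,total,-8.8,1.4
C7:G24,HB1,-4.8,1.1
C7:G24,HB2,-4.4,0.6
C7:G24,HB3,-4.9,0.9
C7:G24,ES1,-2.2,0.4
C7:G24,ES2,-1.0,0.5
C7:G24,rest,-4.4,1.2
C7:G24,total,-21.7,2.3
G8:T23,HB1,-3.5,1.1
G8:T23,HB2,-4.3,0.9
G8:T23,CO..H,-1.1,0.4
G8:T23,ES1,-2.7,0.4
G8:T23,rest,-2.2,0.9
G8:T23,total,-13.8,1.6
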