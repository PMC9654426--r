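pair,method,bb,bf,fb,ff
C7:G24,mm_vacuum,14.9,0.4,2.9,-26.4
A13:T18,mm_vacuum,12.6,3.8,2.4,-9.9
G6:C25,mm_vacuum,14.2,3.2,0.3,-26.7
A3:T28,mm_vacuum,12.6,3.8,2.4,-10.0
A2:T29,mm_vacuum,12.8,3.8,2.5,-10.0
G8:T23,mm_vacuum,14.4,3.3,3.4,-13.3
G10:Arg180,mm_vacuum,1.8,-69.9,0.1,-2.6
C9:Arg180,mm_vacuum,5.1,-54.9,0.4,-4.2
G24:Phe101,mm_vacuum,-0.8,-2.3,-0.2,-1.9
C7:Phe101,mm_vacuum,0.7,0.0,-0.6,-0.7
Gly78:Tyr96,mm_vacuum,-0.2,-4.5,,
Trp82:Lys86,mm_vacuum,-3.9,-4.8,-0.7,-3.0
Trp82:Met107,mm_vacuum,0.0,0.0,-0.1,-0.6
Lys86:Asp108,mm_vacuum,0.1,1.3,-4.7,-101.8
Met107:Asp108,mm_vacuum,-23.0,-1.6,-1.5,-1.5
C7:G24,qm_solute,10.6,2.6,3.4,-30.4
A13:T18,qm_solute,10.4,4.9,2.7,-7.9
G6:C25,qm_solute,10.2,3.9,2.3,-30.2
A3:T28,qm_solute,10.4,4.8,2.6,-7.9
A2:T29,qm_solute,10.6,4.9,2.8,-7.9
G8:T23,qm_solute,10.9,4.1,5.5,-15.4
G10:Arg180,qm_solute,-0.1,-57.8,-0.0,-6.8
C9:Arg180,qm_solute,-0.4,-41.9,-0.0,-8.1
G24:Phe101,qm_solute,-0.8,-1.4,-0.2,-3.3
C7:Phe101,qm_solute,0.0,-0.2,-0.5,-0.3
Gly78:Tyr96,qm_solute,-0.3,-6.7,,
Trp82:Lys86,qm_solute,-6.9,-5.5,-0.8,-2.4
Trp82:Met107,qm_solute,0.0,0.0,-0.3,-1.1
Lys86:Asp108,qm_solute,0.0,0.5,4.3,-109.7
Met107:Asp108,qm_solute,-0.9,-0.1,-1.6,-2.2
C7:G24,qm_solution,0.1,0.2,0.0,-21.7
A13:T18,qm_solution,0.1,0.0,-0.2,-8.8
G6:C25,qm_solution,0.1,-0.1,0.2,-23.0
A3:T28,qm_solution,0.1,0.0,-0.2,-8.8
A2:T29,qm_solution,0.1,0.0,-0.2,-8.9
G8:T23,qm_solution,0.1,0.1,0.1,-13.8
G10:Arg180,qm_solution,-0.1,-20.1,0.0,-0.1
C9:Arg180,qm_solution,0.0,-11.8,0.0,-0.8
G24:Phe101,qm_solution,-0.1,-1.0,-0.1,-2.9
C7:Phe101,qm_solution,0.0,-0.1,-0.1,-0.4
Gly78:Tyr96,qm_solution,0.0,-6.7,,
Trp82:Lys86,qm_solution,-6.2,-1.5,-0.6,-3.9
Trp82:Met107,qm_solution,0.0,0.0,-0.2,-1.1
Lys86:Asp108,qm_solution,0.0,0.0,1.3,-41.5
Met107:Asp108,qm_solution,-1.7,-1.8,-1.7,-0.1
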