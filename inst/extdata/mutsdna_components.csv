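pair,is_covalent,mm_elec,mm_elec_sd,mm_vdw,mm_vdw_sd,pa_es,pa_es_sd,pa_di,pa_di_sd,pa_solv,pa_solv_sd
C7:G24,FALSE,-8.6,2.8,0.2,1.9,-10.1,2.7,-3.7,0.2,-7.6,1.7
A13:T18,FALSE,9.5,1.9,-0.8,1.2,13.1,1.7,-2.9,0.3,-18.9,1.2
G6:C25,FALSE,-9.3,2.8,0.2,1.8,-10.0,2.8,-3.7,0.2,-9.0,1.5
A3:T28,FALSE,9.4,1.7,-0.6,1.2,12.8,1.8,-2.9,0.2,-18.7,1.4
A2:T29,FALSE,9.9,1.9,-0.9,1.3,13.3,1.7,-2.9,0.3,-19.3,1.4
G8:T23,FALSE,8.5,1.5,-0.7,1.1,8.0,1.8,-2.7,0.3,-18.7,1.5
G10:Arg180,FALSE,-70.7,3.2,0.1,1.3,-61.4,3.9,-3.2,0.3,44.4,2.3
C9:Arg180,FALSE,-52.6,2.7,-1.0,0.3,-49.3,3.2,-1.2,0.2,37.9,2.2
G24:Phe101,FALSE,-1.9,0.3,-3.4,0.5,-1.9,0.9,-3.8,0.5,1.6,0.9
C7:Phe101,FALSE,0.0,0.3,-0.6,0.3,-0.5,1.0,-0.5,0.2,0.4,1.0
Gly78:Tyr96,FALSE,-4.7,1.9,-0.2,0.9,-5.8,1.7,-1.2,0.2,0.2,0.5
Trp82:Lys86,FALSE,-9.5,1.2,-2.9,0.8,-11.1,2.7,-4.6,0.6,3.4,2.0
Trp82:Met107,FALSE,-0.2,0.1,-0.5,0.6,-0.2,0.1,-1.2,0.2,0.1,0.1
Lys86:Asp108,FALSE,-106.5,4.4,1.5,1.7,-102.9,3.9,-1.9,0.2,64.6,3.3
Met107:Asp108,TRUE,-26.8,1.5,-0.8,0.8,-0.4,2.3,-4.5,0.3,-0.5,1.8
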