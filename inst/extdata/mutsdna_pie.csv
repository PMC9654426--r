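pair,category,is_covalent,mm_solute_res,mm_solute_res_sd,pa_solute_res,pa_solute_res_sd,pa_solution_res,pa_solution_res_sd,pa_solution_frag,pa_solution_frag_sd,fmo_solution_frag,fmo_solution_frag_sd
C7:G24,nuc-nuc,FALSE,-8.3,1.8,-13.7,2.7,-21.3,2.3,-21.3,2.3,-21.7,2.1
A13:T18,nuc-nuc,FALSE,8.8,1.4,10.1,1.8,-8.8,1.4,-8.8,1.4,-8.9,1.1
G6:C25,nuc-nuc,FALSE,-9.0,1.6,-13.7,2.8,-22.8,2.1,-22.7,2.1,-23.4,1.6
A3:T28,nuc-nuc,FALSE,8.8,1.3,9.9,1.9,-8.8,1.2,-8.7,1.2,-8.9,1.2
A2:T29,nuc-nuc,FALSE,9.1,1.3,10.4,1.7,-8.9,1.2,-8.8,1.2,-8.9,1.1
G8:T23,nuc-nuc,FALSE,7.8,1.2,5.3,1.8,-13.4,1.6,-13.5,1.6,-13.0,1.5
G10:Arg180,nuc-aa,FALSE,-70.6,2.6,-64.7,4.0,-20.2,3.0,1.9,0.5,-1.5,0.5
C9:Arg180,nuc-aa,FALSE,-53.6,2.7,-50.5,3.2,-12.6,2.0,-33.3,2.9,-32.9,2.8
G24:Phe101,nuc-aa,FALSE,-5.3,0.6,-5.8,1.1,-4.2,0.6,-3.9,0.6,-4.1,0.5
C7:Phe101,nuc-aa,FALSE,-0.6,0.4,-1.0,1.1,-0.6,0.3,-0.6,0.3,0.1,0.5
Gly78:Tyr96,aa-aa,FALSE,-4.9,1.6,-7.0,1.7,-6.7,1.8,-0.6,0.2,-0.6,0.3
Trp82:Lys86,aa-aa,FALSE,-12.4,1.2,-15.7,2.8,-12.3,1.5,-6.1,0.9,-4.8,1.0
Trp82:Met107,aa-aa,FALSE,-0.7,0.6,-1.4,0.3,-1.3,0.3,-1.4,0.3,-1.2,0.2
Lys86:Asp108,aa-aa,FALSE,-105.1,3.2,-104.9,4.0,-40.2,3.7,-40.2,3.7,-43.1,3.9
Met107:Asp108,aa-aa,TRUE,-27.6,1.6,-4.9,2.3,-5.4,0.8,-5.9,0.9,-394.0,14.5
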