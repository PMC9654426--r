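residue,residue_type,category,formal_charge,mm_total,qm_res_total,qm_res_total_sd,qm_frag_total,qm_frag_total_sd,mm_funct,qm_res_funct,qm_res_funct_sd
A2,A,nuc,-1,-1.0,-0.990,0.035,-0.988,0.023,-0.105,-0.155,0.017
A3,A,nuc,-1,-1.0,-0.986,0.033,-0.987,0.022,-0.105,-0.153,0.016
G6,G,nuc,-1,-1.0,-1.025,0.034,-1.024,0.021,-0.089,-0.195,0.018
C7,C,nuc,-1,-1.0,-0.967,0.036,-0.956,0.027,-0.063,-0.141,0.018
G8,G,nuc,-1,-1.0,-1.012,0.034,-1.014,0.022,-0.089,-0.191,0.016
C9,C,nuc,-1,-1.0,-0.957,0.035,-0.918,0.024,-0.063,-0.148,0.016
G10,G,nuc,-1,-1.0,-0.955,0.033,-0.970,0.029,-0.089,-0.189,0.017
A13,A,nuc,-1,-1.0,-0.990,0.033,-0.983,0.023,-0.105,-0.154,0.016
T18,T,nuc,-1,-1.0,-1.018,0.027,-1.018,0.018,-0.127,-0.205,0.014
T23,T,nuc,-1,-1.0,-0.986,0.032,-0.985,0.022,-0.127,-0.193,0.016
G24,G,nuc,-1,-1.0,-0.994,0.037,-0.967,0.028,-0.089,-0.195,0.020
C25,C,nuc,-1,-1.0,-0.941,0.030,-0.964,0.022,-0.063,-0.144,0.018
T28,T,nuc,-1,-1.0,-1.012,0.034,-1.015,0.021,-0.127,-0.204,0.017
T29,T,nuc,-1,-1.0,-1.017,0.033,-1.009,0.022,-0.127,-0.205,0.017
Gly78,GLY,aa,0,0.0,-0.014,0.038,-0.015,0.019,,,
Trp82,TRP,aa,0,0.0,0.016,0.040,0.009,0.018,0.029,0.038,0.010
Lys86,LYS,aa,1,1.0,0.956,0.037,0.929,0.027,1.026,0.981,0.018
Tyr96,TYR,aa,0,0.0,-0.009,0.037,-0.020,0.022,0.028,0.010,0.013
Phe101,PHE,aa,0,0.0,-0.003,0.033,-0.012,0.019,0.019,0.014,0.009
Met107,MET,aa,0,0.0,-0.003,0.034,-0.007,0.023,0.050,0.041,0.010
Asp108,ASP,aa,-1,-1.0,-0.921,0.035,-0.917,0.022,-0.858,-0.911,0.015
Arg180,ARG,aa,1,1.0,0.924,0.043,0.914,0.025,1.036,0.943,0.015
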