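task,REC,DET,LMAX,ENT,LAM,TT
jazz,19.47,0.02,1.17,2.52,0.03,22.07
classic,34.22,0.07,3.27,5.08,0.29,58.9
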