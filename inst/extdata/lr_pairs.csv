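pathway,ligand,receptors
BMP,Bmp2,Bmpr1a;Bmpr2
BMP,Bmp4,Bmpr1a;Bmpr2
BMP,Bmp5,Acvr1;Bmpr2
TNF,Tnf,Tnfrsf1a
TNF,Tnf,Tnfrsf1b
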