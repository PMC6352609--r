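channel,x,y,weight
FC5,-0.59,0.31,0.582986
FC3,-0.36,0.33,0.636978
FC1,-0.17,0.34,0.502703
FCz,0,0.35,0.315669
FC2,0.17,0.34,0.165637
FC4,0.36,0.33,0.060686
FC6,0.59,0.31,0.012368
C5,-0.63,0,0.805801
C3,-0.4,0,1
C1,-0.2,0,0.849366
Cz,0,0,0.52045
C2,0.2,0,0.230066
C4,0.4,0,0.07337
C6,0.63,0,0.013165
CP5,-0.59,-0.31,0.582986
CP3,-0.36,-0.33,0.636978
CP1,-0.17,-0.34,0.502703
CPz,0,-0.35,0.315669
CP2,0.17,-0.34,0.165637
CP4,0.36,-0.33,0.060686
CP6,0.59,-0.31,0.012368
P3,-0.37,-0.64,0.187213
P1,-0.18,-0.66,0.138691
Pz,0,-0.67,0.0833
P2,0.18,-0.66,0.042808
P4,0.37,-0.64,0.016709
PO3,-0.27,-0.83,0.056089
POz,0,-0.85,0.027268
PO4,0.27,-0.83,0.009618
O1,-0.28,-0.95,0.023696
Oz,0,-1,0.008785
O2,0.28,-0.95,0.003807
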