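# Cancer-scenario preset: breast
cancer: breast
lambda_T1Tr: 6  # [1/d] Q-induced Th1->Treg conversion scale
zeta_Tb: 4000000  # [cm^3/g] TGF-beta inhibition of CD8 killing
t0: 14  # [d] treatment start
horizon: 56  # [d] final day
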