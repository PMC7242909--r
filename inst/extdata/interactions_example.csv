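id,partner_a,partner_b,annotation
IL6_IL6R,Il6,Il6ra+Il6st,cytokine receptor complex
CXCL12_CXCR4,Cxcl12,Cxcr4,chemokine axis
TGFB1_TGFBR,Tgfb1,Tgfbr1+Tgfbr2,growth factor complex
CSF1_CSF1R,Csf1,Csf1r,myeloid growth factor
DLL1_NOTCH1,Dll1,Notch1,juxtacrine
PDGFA_PDGFRA,Pdgfa,Pdgfra,stromal growth factor
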