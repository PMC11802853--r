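ligand,receptor,tag
CCL17,CCR4,chemokine
CCL22,CCR4,chemokine
CCL1,CCR8,chemokine
CXCL12,CXCR4,chemokine
CXCL16,CXCR6,chemokine
CXCL9,CXCR3,chemokine
CXCL10,CXCR3,chemokine
CXCL13,CXCR5,chemokine
CCL5,CCR5,chemokine
CCL2,CCR2,chemokine
CCL3,CCR1,chemokine
CCL4,CCR5,chemokine
IL2,IL2RA,cytokine
IL2,IL2RB,cytokine
IL15,IL2RB,cytokine
IL10,IL10RA,cytokine
TGFB1,TGFBR1,cytokine
IL6,IL6R,cytokine
TNF,TNFRSF1A,cytokine
IL7,IL7R,cytokine
IL4,IL4R,cytokine
IL21,IL21R,cytokine
CSF1,CSF1R,cytokine
CSF2,CSF2RA,cytokine
IL1B,IL1R1,cytokine
FLT3LG,FLT3,cytokine
CD80,CTLA4,checkpoint
CD86,CTLA4,checkpoint
CD80,CD28,costimulation
CD86,CD28,costimulation
CD274,PDCD1,checkpoint
PDCD1LG2,PDCD1,checkpoint
LGALS9,HAVCR2,checkpoint
ICOSLG,ICOS,costimulation
CD40LG,CD40,costimulation
TNFSF13B,TNFRSF13B,cytokine
XCL1,XCR1,chemokine
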