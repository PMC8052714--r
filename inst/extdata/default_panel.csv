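"name","klass"
"EGF","cytokine"
"EOTAXIN","cytokine"
"FGF-2","cytokine"
"FLT-3L","cytokine"
"FRACTALKINE","cytokine"
"G-CSF","cytokine"
"GM-CSF","cytokine"
"IFNa2","cytokine"
"IFNg","cytokine"
"IL-10","cytokine"
"IL-12p40","cytokine"
"IL-12p70","cytokine"
"IL-13","cytokine"
"IL-15","cytokine"
"IL-17A","cytokine"
"IL-1a","cytokine"
"IL-1b","cytokine"
"IL-1ra","cytokine"
"IL-2","cytokine"
"IL-3","cytokine"
"IL-4","cytokine"
"IL-5","cytokine"
"IL-6","cytokine"
"IL-7","cytokine"
"IL-8","cytokine"
"IL-9","cytokine"
"IP-10","cytokine"
"MCP-1","cytokine"
"MCP-3","cytokine"
"MIP-1a","cytokine"
"MIP-1b","cytokine"
"TGFa","cytokine"
"TNFa","cytokine"
"TNFb","cytokine"
"VEGF","cytokine"
"CD11c+","cell"
"CD11c/CD14+","cell"
"CD11c/CD86+","cell"
"CD11c/HLA-DR+","cell"
"CD123/HLA-DR+","cell"
"CD14/CD197+","cell"
"CD16/CD56+","cell"
"CD3+","cell"
"CD3/CD4+","cell"
"CD3/CD62L+","cell"
"CD3/CD69+","cell"
"CD3/CD8+","cell"
"CD4/CD294+","cell"
"CD4/TIM3+","cell"
"CD56+","cell"
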