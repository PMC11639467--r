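# Cell-type term list — reconstructed SAMPLE for synthetic corpora and examples.
erythrocytes
neutrophils
t-lymphocytes
b-lymphocytes
blood cells
leucocytes
monocytes
macrophages
blood platelets
podocytes
fibroblasts
endothelial cells
epithelial cells
dendritic cells
killer cells, natural
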