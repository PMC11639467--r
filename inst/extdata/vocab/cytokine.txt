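# Cytokine term list — reconstructed SAMPLE for synthetic corpora and examples.
erythropoietin
interleukin-6
interleukin-1beta
interleukin-8
interleukin-10
transforming growth factor beta
transforming growth factor beta1
tumour necrosis factor-alpha
fibroblast growth factor-23
interferon-gamma
vascular endothelial growth factor a
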