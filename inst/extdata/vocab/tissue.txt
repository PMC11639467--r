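# Tissue term list — reconstructed SAMPLE for synthetic corpora and examples.
kidney
kidney glomerulus
kidney tubules
kidney cortex
kidney medulla
nephrons
renal artery
bone and bones
myocardium
liver
spleen
urinary bladder
blood vessels
connective tissue
bone marrow
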