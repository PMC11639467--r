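# Method term list — reconstructed SAMPLE for synthetic corpora and examples.
glomerular filtration rate
blood pressure
kidney function tests
biopsy
ultrasonography
radiography
renal dialysis
haemodialysis
kidney transplantation
urinalysis
biomarkers
enzyme-linked immunosorbent assay
polymerase chain reaction
flow cytometry
magnetic resonance imaging
tomography, x-ray computed
immunohistochemistry
mass spectrometry
electrophoresis
survival analysis
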