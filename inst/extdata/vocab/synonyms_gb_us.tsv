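# American -> British spelling unification for shipped term lists.
anemia	anaemia
hemorrhage	haemorrhage
diarrhea	diarrhoea
edema	oedema
dyspnea	dyspnoea
uremia	uraemia
ischemia	ischaemia
hemodialysis	haemodialysis
leukocytes	leucocytes
tumor necrosis factor-alpha	tumour necrosis factor-alpha
hyperphosphatemia	hyperphosphataemia
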