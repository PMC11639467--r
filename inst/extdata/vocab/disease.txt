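# Disease term list — reconstructed SAMPLE (synthetic corpora and examples
# only; the full controlled vocabulary has thousands of terms).
kidney failure, chronic
kidney diseases
renal insufficiency, chronic
acute kidney injury
hypertension
uraemia
renal artery obstruction
diabetes mellitus
diabetes mellitus, type 2
obesity
cardiovascular diseases
peritonitis
ischaemia
glomerulonephritis
nephritis
polycystic kidney diseases
hyperparathyroidism
amyloidosis
nephrosclerosis
pyelonephritis
urolithiasis
hyperphosphataemia
metabolic acidosis
proteinuria
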