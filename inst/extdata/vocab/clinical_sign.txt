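# Clinical-sign term list (28 terms) for renal-disease literature mining.
# Reconstructed default: the core signs are those central to CKD reporting;
# the remainder are plausible renal clinical signs added to complete the
# 28-term universe. Replace with a published list for real corpora.
anaemia
vomiting
haemorrhage
polyuria
anuria
polydipsia
lethargy
anorexia
abdominal pain
melena
oral ulcer
asthenia
nausea
diarrhoea
fatigue
weight loss
appetite loss
weakness
pruritus
oedema
dyspnoea
dehydration
constipation
cachexia
halitosis
muscle cramp
dysgeusia
seizure
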