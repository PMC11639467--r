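# Pain-type term list for renal-disease literature mining.
# Reconstructed default covering the pain types mined in CKD corpora;
# user-replaceable.
pain
abdominal pain
headache
neck pain
chronic pain
arthralgia
chest pain
musculoskeletal pain
back pain
low back pain
flank pain
pelvic pain
neuralgia
acute pain
breakthrough pain
nociceptive pain
visceral pain
myalgia
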