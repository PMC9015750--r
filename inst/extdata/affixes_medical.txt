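# Common medical affixes.  Lines ending in '-' are prefixes; lines starting
# with '-' are suffixes.
hyper-
hypo-
brady-
tachy-
cardio-
neuro-
hemo-
osteo-
gastro-
derma-
nephro-
hepato-
pneumo-
myo-
poly-
anti-
dys-
peri-
endo-
-itis
-osis
-emia
-ectomy
-otomy
-ology
-pathy
-algia
-plegia
-sclerosis
-trophy
-penia
-megaly
-gram
-scopy
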