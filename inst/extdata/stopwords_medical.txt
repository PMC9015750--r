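# Medical stop words: common clinical tokens that should never be linked or
# annotated.  One token per line; user-overridable.
patient
patients
doctor
physician
nurse
hospital
clinic
history
exam
examination
normal
negative
positive
stable
mild
moderate
severe
acute
chronic
daily
dose
mg
ml
left
right
bilateral
visit
report
results
status
plan
follow
followup
review
noted
denies
presents
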