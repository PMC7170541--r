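# Diagnosis lexicon: surface term = ICD-10 category block.
# Blocks: F00-F03 (dementia), F20-F29 (psychosis), other-F (any other F code).
dementia = F00-F03
alzheimer's disease = F00-F03
alzheimers disease = F00-F03
vascular dementia = F00-F03
mixed dementia = F00-F03
lewy body dementia = F00-F03
dementia with lewy bodies = F00-F03
frontotemporal dementia = F00-F03
schizophrenia = F20-F29
schizoaffective disorder = F20-F29
psychosis = F20-F29
psychotic disorder = F20-F29
delusional disorder = F20-F29
depressive episode = other-F
depression = other-F
bipolar affective disorder = other-F
generalised anxiety disorder = other-F
delirium = other-F
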