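# Antipsychotic dictionary: surface form = normalized generic name.
# Whole-word, case-insensitive matching; brands map to generics.
risperidone = risperidone
olanzapine = olanzapine
quetiapine = quetiapine
haloperidol = haloperidol
aripiprazole = aripiprazole
amisulpride = amisulpride
sulpiride = sulpiride
promazine = promazine
clozapine = clozapine
chlorpromazine = chlorpromazine
zuclopenthixol = zuclopenthixol
paliperidone = paliperidone
lurasidone = lurasidone
risperdal = risperidone
zyprexa = olanzapine
seroquel = quetiapine
haldol = haloperidol
abilify = aripiprazole
largactil = chlorpromazine
clopixol = zuclopenthixol
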