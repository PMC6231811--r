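# prescribed medications used to treat mental health disorders
# canonical = brand/generic name; class attribute = medication class
xanax	Xanax	class=antianxiety
valium	Valium	class=antianxiety
diazepam	Diazepam	class=antianxiety
alprazolam	Alprazolam	class=antianxiety
tensium	Tensium	class=antianxiety
zoloft	Zoloft	class=antidepressant
prozac	Prozac	class=antidepressant
lexapro	Lexapro	class=antidepressant
escitalopram	Escitalopram	class=antidepressant
sertraline	Sertraline	class=antidepressant
anafranil	Anafranil	class=antidepressant
endep	Endep	class=antidepressant
cymbalta	Cymbalta	class=antidepressant
effexor	Effexor	class=antidepressant
clozapine	Clozapine	class=antipsychotic
risperdal	Risperdal	class=antipsychotic
risperidone	Risperidone	class=antipsychotic
seroquel	Seroquel	class=antipsychotic
quetiapine	Quetiapine	class=antipsychotic
olanzapine	Olanzapine	class=antipsychotic
zyprexa	Zyprexa	class=antipsychotic
abilify	Abilify	class=antipsychotic
stelazine	Stelazine	class=neuroleptic
haloperidol	Haloperidol	class=neuroleptic
largactil	Largactil	class=neuroleptic
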