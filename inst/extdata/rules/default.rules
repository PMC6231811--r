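# Default extraction rules: role-anchored lexical patterns over gazetteer
# lookups. Each block needs a rule id, a role (POI | victim) and a pattern.
# not(negation) windows between the anchor and the disorder slot implement
# negation exclusion: a negated context cannot be bridged, so the rule does
# not fire. Windows are capped at 3 tokens to protect precision. Matching is
# sentence-bounded; a comma/"and" enumeration after the capture slot emits
# one mention per listed disorder.

# --- POI ---------------------------------------------------------------

# "accused is suffering from schizophrenia", "defendant suffers from ...",
# "POI was diagnosed with ...", "POI abuses alcohol"
rule poi_verb_disorder
role POI
pattern lookup(poi) not(negation)[0,1] lookup(be)[0,1] lookup(verbs) literal(from)[0,1] literal(with)[0,1] not(negation)[0,2] capture(mental_disorder|drug_addiction)

# "POI takes Valium", "accused takes a number of antidepressants"
rule poi_takes_medication
role POI
pattern lookup(poi) not(negation)[0,1] lookup(verbs) not(negation)[0,3] capture(drug_names|drug_types)

# "POI has a history of depression, self-harm, and suicidal tendencies"
rule poi_have_history
role POI
pattern lookup(poi) not(negation)[0,1] lookup(have) lookup(history) capture(mental_disorder|drug_addiction)

# "POI with a history of depression", "defendant, hx of self-harm"
rule poi_history
role POI
pattern lookup(poi) not(negation)[0,1] lookup(history) capture(mental_disorder|drug_addiction)

# "POI has depression"
rule poi_have_disorder
role POI
pattern lookup(poi) not(negation)[0,1] lookup(have) not(negation)[0,2] capture(mental_disorder)

# "POI is schizophrenic"
rule poi_is_adjective
role POI
pattern lookup(poi) not(negation)[0,1] lookup(be) not(negation)[0,1] capture(adjectives)

# "POI is addicted to heroin"
rule poi_addicted_to
role POI
pattern lookup(poi) not(negation)[0,1] lookup(be) literal(addicted) literal(to) capture(drug_addiction|drug_names)

# "... the POI due to his alcoholism"
rule poi_due_to
role POI
pattern lookup(poi) literal(due) literal(to) not(negation)[0,2] capture(mental_disorder)

# --- victim ------------------------------------------------------------

rule vic_verb_disorder
role victim
pattern lookup(victim) not(negation)[0,1] lookup(be)[0,1] lookup(verbs) literal(from)[0,1] literal(with)[0,1] not(negation)[0,2] capture(mental_disorder|drug_addiction)

rule vic_takes_medication
role victim
pattern lookup(victim) not(negation)[0,1] lookup(verbs) not(negation)[0,3] capture(drug_names|drug_types)

rule vic_have_history
role victim
pattern lookup(victim) not(negation)[0,1] lookup(have) lookup(history) capture(mental_disorder|drug_addiction)

rule vic_history
role victim
pattern lookup(victim) not(negation)[0,1] lookup(history) capture(mental_disorder|drug_addiction)

rule vic_have_disorder
role victim
pattern lookup(victim) not(negation)[0,1] lookup(have) not(negation)[0,2] capture(mental_disorder)

rule vic_is_adjective
role victim
pattern lookup(victim) not(negation)[0,1] lookup(be) not(negation)[0,1] capture(adjectives)

rule vic_addicted_to
role victim
pattern lookup(victim) not(negation)[0,1] lookup(be) literal(addicted) literal(to) capture(drug_addiction|drug_names)

# "... violent with the victims due to her alcoholism" -- deliberately kept:
# replicates the documented role-misattribution failure mode
rule vic_due_to
role victim
pattern lookup(victim) literal(due) literal(to) not(negation)[0,2] capture(mental_disorder)
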