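# adjectives indicating a mental disorder; canonical = standardized disorder
alcoholic	Alcoholism
schizophrenic	Schizophrenia
bipolar	Bipolar disorder
autistic	Autism
depressed	Depression
anorexic	Anorexia nervosa
bulimic	Bulimia nervosa
suicidal	Suicidal ideation
delusional	Delusional disorder
paranoid	Paranoia
demented	Dementia
anxious	Anxiety
psychotic	Psychosis
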