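# mental_disorder: disorder terms (official ICD-10 rubrics, unofficial
# variants, abbreviations, descriptive phrases, common misspellings).
# Format: term <TAB> canonical form <TAB> key=value attributes.
# Entries with misspelling=true are deliberate misspellings of the canonical;
# entries with phrase=true are verb-bearing phrases the synthetic generator
# must not plant into noun slots.
depression	Depression
depresion	Depression	misspelling=true
depressive disorder	Depression
major depression	Depression
clinical depression	Depression
severe depression	Depression
postnatal depression	Postpartum depression
post natal depression	Postpartum depression
postpartum depression	Postpartum depression
bipolar disorder	Bipolar disorder
bipolar	Bipolar disorder
bi-polar	Bipolar disorder
manic depression	Bipolar disorder
manic episode	Manic episode
manic episodes	Manic episode
mood disorder	Mood disorder
mood disorders	Mood disorder
persistent mood disorder	Persistent mood disorder
cyclothymic disorder	Cyclothymic disorder
dysthymia	Dysthymia
schizophrenia	Schizophrenia
schitzophrenia	Schizophrenia	misspelling=true
scitzophrenia	Schizophrenia	misspelling=true
skitzophrenia	Schizophrenia	misspelling=true
schizofrenia	Schizophrenia	misspelling=true
paranoid schizophrenia	Paranoid schizophrenia
schizoaffective disorder	Schizoaffective disorder
schizotypal disorder	Schizotypal disorder
delusions	Delusional disorder
delusional disorder	Delusional disorder
psychosis	Psychosis
psychotic episode	Psychosis
psychotic episodes	Psychosis
anxiety	Anxiety
anxeity	Anxiety	misspelling=true
anxiety disorder	Anxiety
anxiety issues	Anxiety
generalized anxiety disorder	Generalized anxiety disorder
generalised anxiety disorder	Generalized anxiety disorder
panic disorder	Panic disorder
panic attacks	Panic disorder
panic attack	Panic disorder
phobia	Phobia
social phobia	Phobia
ptsd	Posttraumatic stress disorder
posttraumatic stress disorder	Posttraumatic stress disorder
post-traumatic stress disorder	Posttraumatic stress disorder
post traumatic stress disorder	Posttraumatic stress disorder
adjustment disorder	Adjustment disorder
ocd	Obsessive-compulsive disorder
obsessive-compulsive disorder	Obsessive-compulsive disorder
obsessive compulsive disorder	Obsessive-compulsive disorder
dissociative disorder	Dissociative disorder
dissociative identity disorder	Dissociative identity disorder
split personality disorder	Dissociative identity disorder
multiple personality disorder	Dissociative identity disorder
body dysmorphic disorder	Body dysmorphic disorder
eating disorder	Eating disorder
eating disorders	Eating disorder
anorexia	Anorexia nervosa
anorexia nervosa	Anorexia nervosa
bulimia	Bulimia nervosa
bulimia nervosa	Bulimia nervosa
personality disorder	Personality disorder
borderline personality disorder	Borderline personality disorder
paranoid personality disorder	Paranoid personality disorder
antisocial personality disorder	Antisocial personality disorder
narcissism	Narcissistic
narcissistic personality disorder	Narcissistic
kleptomania	Kleptomania
intermittent explosive disorder	Intermittent explosive disorder
anger issues	Anger issues
anger management issues	Anger issues
intellectual disability	Intellectual disability
intellectual disabilities	Intellectual disability
mild intellectual disability	Mild intellectual disability
severe intellectual disability	Severe intellectual disability
adhd	Attention deficit hyperactivity disorder
attention deficit hyperactivity disorder	Attention deficit hyperactivity disorder
attention deficit disorder	Attention deficit hyperactivity disorder
conduct disorder	Conduct disorder
oppositional defiant disorder	Oppositional defiance disorder
oppositional defiance disorder	Oppositional defiance disorder
tic disorder	Tic disorder
transient tic disorder	Tic disorder
autism	Autism
autism spectrum disorder	Autism
autistic spectrum disorder	Autism
asperger syndrome	Asperger syndrome
asperger's syndrome	Asperger syndrome
aspergers	Asperger syndrome
aspergus syndrome	Asperger syndrome	misspelling=true
mathematics disorder	Mathematics disorder
phonological disorder	Phonological disorder
self-harm	Self-harm
self harm	Self-harm
self-harming	Self-harm
self-harming issues	Self-harm
self harming issues	Self-harm
self-harmed	Self-harm	phrase=true
cut herself	Self-harm	phrase=true
cut himself	Self-harm	phrase=true
cuts herself	Self-harm	phrase=true
cut herself on purpose	Self-harm	phrase=true
suicidal ideation	Suicidal ideation
suicidal ideations	Suicidal ideation
suicidal thoughts	Suicidal ideation
suicidal tendencies	Suicidal ideation
suicidal	Suicidal ideation
suicide attempt	Suicide attempt
multiple suicide attempts	Suicide attempt
attempted suicide	Suicide attempt	phrase=true
attempted to kill himself	Suicide attempt	phrase=true
attempted to kill herself	Suicide attempt	phrase=true
alcoholism	Alcoholism
alcohol abuse	Alcoholism
alcohol addiction	Alcoholism
alcohol dependence	Alcoholism
alcohol problem	Alcoholism
alcohol-related disorder	Alcoholism
drinking problem	Alcoholism
abuses alcohol	Alcoholism	phrase=true
cannabis addiction	Cannabis abuse
cannabis abuse	Cannabis abuse
nicotine dependence	Nicotine dependence
substance abuse	Substance abuse
substance abuse problem	Substance abuse
drug abuse	Substance abuse
drug problem	Substance abuse
drug habit	Substance abuse
ongoing drug abuse problems	Substance abuse
dementia	Dementia
unspecified dementia	Dementia
vascular dementia	Vascular dementia
alzheimer disease	Alzheimer disease
alzheimer's disease	Alzheimer disease
alzheimers	Alzheimer disease
frontotemporal dementia	Frontotemporal dementia
huntington disease	Huntington disease
huntington's disease	Huntington disease
down syndrome	Down syndrome
brain damage	Traumatic brain injury
brain injury	Traumatic brain injury
serious brain injury	Traumatic brain injury
brain trauma	Traumatic brain injury
traumatic brain injury	Traumatic brain injury
acquired brain injury	Traumatic brain injury
neurological disorder	Neurological disorder
mental health issues	Unspecified mental disorder
mental health issue	Unspecified mental disorder
mental health problems	Unspecified mental disorder
mental health problem	Unspecified mental disorder
mental illness	Unspecified mental disorder
mental condition	Unspecified mental disorder
mental disorder	Unspecified mental disorder
mental health disorder	Unspecified mental disorder
mental health concerns	Unspecified mental disorder
severe mental disorder	Unspecified mental disorder
psychiatric issues	Unspecified mental disorder
psychiatric condition	Unspecified mental disorder
psychological issues	Unspecified mental disorder
drug-induced disorder	Drug-induced disorder
drug induced disorder	Drug-induced disorder
drug-induced psychosis	Drug-induced disorder
drug induced psychosis	Drug-induced disorder
drug-induced mental health problem	Drug-induced disorder
prescription drug abuse	Prescription drug abuse
abusing prescribed medication	Prescription drug abuse	phrase=true
addiction to prescribed medications	Prescription drug abuse	phrase=true
addicted to prescription medication	Prescription drug abuse	phrase=true
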