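term	category
Depression	Major depressive disorder, single episode
Postpartum depression	Postpartum depression
Bipolar disorder	Bipolar disorder, unspecified
Manic episode	Manic episode
Mood disorder	Mood (affective) disorders
Persistent mood disorder	Persistent mood disorder
Cyclothymic disorder	Cyclothymic disorder
Dysthymia	Dysthymia
Schizophrenia	Schizophrenia, unspecified
Paranoid schizophrenia	Paranoid schizophrenia
Schizoaffective disorder	Schizoaffective disorders
Schizotypal disorder	Schizotypal disorder
Delusional disorder	Delusional disorders
Psychosis	Unspecified psychosis not due to a substance or known physiological condition
Paranoia	Schizophrenia, schizotypal, delusional, and other non-mood psychotic disorders
Anxiety	Anxiety disorder, unspecified
Generalized anxiety disorder	Generalized anxiety disorder
Panic disorder	Panic disorder
Phobia	Phobic anxiety disorders
Posttraumatic stress disorder	Posttraumatic stress disorder
Adjustment disorder	Adjustment disorder
Obsessive-compulsive disorder	Obsessive-compulsive disorder, unspecified
Dissociative disorder	Dissociative and conversion disorders
Dissociative identity disorder	Dissociative identity disorder
Body dysmorphic disorder	Somatoform disorders
Eating disorder	Eating disorders
Anorexia nervosa	Anorexia nervosa
Bulimia nervosa	Bulimia nervosa
Personality disorder	Personality disorder, unspecified
Borderline personality disorder	Borderline personality disorder
Paranoid personality disorder	Paranoid personality disorder
Antisocial personality disorder	Antisocial personality disorder
Narcissistic	Narcissistic personality disorder
Kleptomania	Kleptomania
Intermittent explosive disorder	Intermittent explosive disorder
Anger issues	Disorders of adult personality and behavior
Intellectual disability	Intellectual disability, unspecified
Mild intellectual disability	Intellectual disability, mild
Severe intellectual disability	Intellectual disability, severe
Attention deficit hyperactivity disorder	Attention deficit hyperactivity disorder
Conduct disorder	Conduct disorder, unspecified
Oppositional defiance disorder	Oppositional defiance disorder
Tic disorder	Tic disorders
Autism	Autism
Asperger syndrome	Asperger syndrome
Mathematics disorder	Pervasive and specific developmental disorders
Phonological disorder	Pervasive and specific developmental disorders
Self-harm	Intentional self-harm
Suicidal ideation	Suicidal ideations
Suicide attempt	Suicide attempt
Alcoholism	Alcohol abuse
Cannabis abuse	Cannabis abuse
Nicotine dependence	Nicotine dependence
Opioid abuse	Other psychoactive substance related disorders
Stimulant abuse	Other stimulant related disorders
Cocaine abuse	Other psychoactive substance related disorders
Substance abuse	Substance abuse (unspecified)
Dementia	Dementia, unspecified
Vascular dementia	Vascular dementia
Alzheimer disease	Alzheimer's disease, unspecified
Frontotemporal dementia	Frontotemporal dementia
Huntington disease	Systemic atrophies primarily affecting the central nervous system
Down syndrome	Down syndrome, unspecified
Traumatic brain injury	Traumatic brain injury
Neurological disorder	Unspecified diseases of the nervous system
Unspecified mental disorder	Unspecified mental disorder
Drug-induced disorder	Unspecified drug-induced disorders
Prescription drug abuse	Drug prescription abuse
Zoloft	Medications-antidepressants
Prozac	Medications-antidepressants
Lexapro	Medications-antidepressants
Escitalopram	Medications-antidepressants
Sertraline	Medications-antidepressants
Anafranil	Medications-antidepressants
Endep	Medications-antidepressants
Cymbalta	Medications-antidepressants
Effexor	Medications-antidepressants
Antidepressant medication	Medications-antidepressants
Xanax	Medications-antianxiety
Valium	Medications-antianxiety
Diazepam	Medications-antianxiety
Alprazolam	Medications-antianxiety
Tensium	Medications-antianxiety
Antianxiety medication	Medications-antianxiety
Antipsychotic medication	Medications-antipsychotics
Clozapine	Medications-antipsychotics
Risperdal	Medications-antipsychotics
Risperidone	Medications-antipsychotics
Seroquel	Medications-antipsychotics
Quetiapine	Medications-antipsychotics
Olanzapine	Medications-antipsychotics
Zyprexa	Medications-antipsychotics
Abilify	Medications-antipsychotics
Mood stabilizer medication	Medications-antipsychotics
Stelazine	Medications-neuroleptics
Haloperidol	Medications-neuroleptics
Largactil	Medications-neuroleptics
Neuroleptic medication	Medications-neuroleptics
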