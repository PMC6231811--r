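# illegal drugs known to cause addiction; canonical = standardized abuse term
cannabis	Cannabis abuse
marijuana	Cannabis abuse
heroin	Opioid abuse
opioids	Opioid abuse
methamphetamine	Stimulant abuse
methamphetamines	Stimulant abuse
amphetamines	Stimulant abuse
ice	Stimulant abuse
speed	Stimulant abuse
ecstasy	Stimulant abuse
cocaine	Cocaine abuse
alcohol	Alcoholism
illicit drugs	Substance abuse
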