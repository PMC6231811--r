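# terms describing a person of interest (POI) in a DV event
poi
accused
defendant
offender
perpetrator
suspect
person of interest
respondent
assailant
abuser
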