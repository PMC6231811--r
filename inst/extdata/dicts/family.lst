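# terms indicating a family relationship
mother
father
cousin
grandfather
grandmother
brother
sister
son
daughter
uncle
aunt
stepfather
stepmother
husband
wife
partner
carer
nephew
niece
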