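# terms describing a victim in a DV event (incl. abbreviations)
victim
victims
vic
pn
pinop
complainant
aggrieved
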