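# conjugations of "have" in present and past tense
has
have
had
having
has had
has been
have been
had been
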