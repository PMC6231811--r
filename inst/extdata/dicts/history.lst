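# variations of mental-health history mentions
a history of
history of
a short history of
a long history of
a past history of
past history of
serious history of
a serious history of
extensive history of
an extensive history of
hx
hx of
h/o
extensive h/o
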