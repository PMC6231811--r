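# verbs in common lexical patterns indicating a mental health disorder
suffering
suffers
suffer
suffered
takes
taking
take
took
admitted
struggles
struggling
appears
diagnosed
experiencing
experienced
battles
battling
uses
using
abuses
abusing
smokes
medicated
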