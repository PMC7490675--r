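name,pattern
genome,genom(e|es|ic|ics|ically)|\bdna\b
baby,bab(y|ies)
disease,disease|illness|disorder
embryo,embryo(s|nic)?
treatment,treat(ment|ments|ed|ing)?|therap(y|ies|eutic)
mutation,mutat(e|ed|es|ing|ion|ions)
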