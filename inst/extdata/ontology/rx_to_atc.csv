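rxcui,atc
161,N02BE
310490,A10BB07
723,J01CA04
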