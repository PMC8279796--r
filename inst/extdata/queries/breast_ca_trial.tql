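varage= AGE(70 YEARS, MAX)

varfemale= GENDER=“FEMALE”

varbcis= INTERSECT(ICD9=“233.0”, NO HISTORY OF(ICD9=“174”))

INTERSECT($bcis,$age,$female)
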