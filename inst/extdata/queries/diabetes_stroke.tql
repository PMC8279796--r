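varstroke= ICD9=“434.91”

varmale_patients_over_65 = INTERSECT(GENDER=”male”, AGE(65 YEARS, MAX))
varglipizide= RX = 310490
varno_history_of_stroke= NO HISTORY OF ($stroke)

vardiabetes= FIRST MENTION(UNION(COUNT(ICD9=“250.00”, 2, MAX),

COUNT(LABS(“4548-4 [%]”, 8, MAX), 2, MAX)))

vardiabetes_no_hx_stroke= INTERSECT($diabetes,$no_history_of_stroke)

vardiabetes_then_glipizide= SEQUENCE($diabetes_no_hx_stroke,$glipizide*)

varglipizide_then_stroke= SEQUENCE($diabetes_then_glipizide,$stroke*)+(-3 MONTHS, 0)

INTERSECT($male_patients_over_65,$glipizide_then_stroke)
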