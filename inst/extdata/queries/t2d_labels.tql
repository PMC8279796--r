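vart2d= FIRST MENTION(UNION(COUNT(ICD9=“250.00”, 2, MAX), COUNT(LABS(“4548-4 [%]”, 8, MAX), 2, MAX)))

vart1d= OR(ICD9=“250.01”, ICD9=“250.03”)

vart2d_no_t1d= INTERSECT($t2d, NOT($t1d))

EXPORT($t2d_no_t1d, TIME=$t2d_no_t1d, “T2D”=$t2d_no_t1d)
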