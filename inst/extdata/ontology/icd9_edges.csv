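child,parent
250.00,250.0
250.01,250.0
250.02,250.0
250.03,250.0
250.0,250
250.1,250
433.1,433
434.91,434.9
434.9,434
434.0,434
435.9,435
466.0,466
466.11,466.1
466.1,466
491.21,491.2
491.2,491
491.9,491
482.9,482
482.0,482
492.8,492
493.20,493.2
493.21,493.2
493.2,493
496.0,496
277.00,277.0
277.01,277.0
277.0,277
153.9,153
153.0,153
174.9,174
174.8,174
233.0,233
401.9,401
401.1,401
272.4,272
780.79,780.7
780.7,780
715.90,715.9
715.9,715
530.81,530.8
530.8,530
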