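icd9	icd10
410.1	I21.0
410.9	I21.9
250.00	E11.9
250.60	E11.40
272.4	E78.5
401.9	I10
724.2	M54.5
493.90	J45.909
311	F32.9
585.9	N18.9
285.9	D64.9
530.81	K21.9
780.52	G47.00
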