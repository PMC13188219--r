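name	start	end
V1	68	98
V2	136	241
V3	432	496
V4	575	681
V5	821	878
V6	985	1042
V7	1116	1172
V8	1242	1293
V9	1434	1464
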