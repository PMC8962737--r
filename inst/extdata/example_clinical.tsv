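patient_id	age	tnm	er	pr	her2	dfs_months	event
Patient1	56	T2N2M0	++	++	-	62	TRUE
Patient2	56	T2N0M0	+	-	-	80	TRUE
Patient3	46	T3N2M0	++	++	-	28	TRUE
Patient4	44	T1N0M0	++	++	-	72	TRUE
Patient5	68	T1N0M0	+++	-	++~++	22	TRUE
Patient6	N.A.	T1N0M0	-	+	++	38	TRUE
Patient7	N.A.	T1N0M0	-	-	+++	42	TRUE
Patient8	58	T2N0M0	++	+	-	24	TRUE
Patient9	30	T1N0M0	-	+	-	5	TRUE
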