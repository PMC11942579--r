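primer_id	sequence	TNB	NPB	PPB_published
UBC807	AGAGAGAGAGAGAGAGT	14	12	85.7
UBC808	AGAGAGAGAGAGAGAGC	12	12	100
UBC809	AGAGAGAGAGAGAGAGG	5	3	60.0
UBC823	TCTCTCTCTCTCTCTCC	13	12	92.3
UBC834	AGAGAGAGAGAGAGAGYT	13	10	76.9
UBC840	GAGAGAGAGAGAGAGAYT	10	9	90.0
UBC842	GAGAGAGAGAGAGAGAYG	11	8	72.7
UBC873	GACAGACAGACAGACA	14	14	100
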