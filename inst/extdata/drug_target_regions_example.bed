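17	61554421	61575741	ACE	ACEI	gene
10	115803624	115806663	ADRB1	BB	gene
12	2162163	2807115	CACNA1C	CCB	gene
3	53529075	53846492	CACNA1D	CCB	gene
10	18429605	18830688	CACNB2	CCB	gene
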