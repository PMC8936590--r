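1	High	O		
2	b-value	B-ACQ_A		
3	fMRI	B-AOB	Produces	[2]
4	was	O		
5	obtained	B-Acq	Trigger	[3,8]
6	through	O		
7	the	O		
8	central	B-BRI	From	
9	sulcus	I-BRI	From	
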