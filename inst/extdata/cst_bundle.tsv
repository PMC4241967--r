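diameter_um	count	myelinated	fraction
2	567000	TRUE	0.5504854
5	105000	TRUE	0.1019417
8	28000	TRUE	0.0271845
11	30000	TRUE	0.0291262
3	300000	FALSE	0.2912621
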