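group	state	total	unique
AML	hyper	122648	9814
Astrocytoma	hyper	110560	1563
Oligodendroglioma	hyper	110335	3350
Breast cancer	hyper	100534	2578
Cholangiocarcinoma	hyper	110231	6089
SNUC	hyper	96787	2922
AML	hypo	100337	7116
Astrocytoma	hypo	100820	1074
Oligodendroglioma	hypo	100100	1752
Breast cancer	hypo	90858	2692
Cholangiocarcinoma	hypo	95628	2412
SNUC	hypo	88332	2825
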