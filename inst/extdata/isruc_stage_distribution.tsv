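dataset	subjects	total	W	N1	N2	N3	R
S1	100	87187	20098	11062	27511	17251	11265
S3	10	8549	1651	1215	2609	2014	1060
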