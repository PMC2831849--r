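@HD	VN:1.6	SO:unsorted
@SQ	SN:Chr5	LN:26975502
pair_0001	99	Chr5	15902154	60	40M	=	15902374	260	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
pair_0001	147	Chr5	15902374	60	40M	=	15902154	-260	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII
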