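FAM1	III2	0	0	1	2	case
FAM1	III3	0	0	2	2	case
FAM1	III4	0	0	1	2	case
FAM1	III5	0	0	2	2	case
FAM1	IV2	III2	0	2	1	possible_carrier
FAM1	III1	0	0	1	1	control
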