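sample_id	group	age	sex	tissue	cohort
EX1	case	8	M	blood	discovery
EX2	case	3	M	blood	discovery
EX3	case	11	M	blood	discovery
EX4	case	15.5	F	blood	discovery
EX5	case	5	F	blood	discovery
EX6	case	10	F	blood	discovery
EX7	case	4.5	M	blood	discovery
EX8	case	10	F	blood	discovery
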