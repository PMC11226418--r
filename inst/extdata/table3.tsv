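row	R2	R3	R4	R5	R6	R7	R8	R9	R10
Sum	113	63	18	105	44	15	26	78	72
Average	6.3	3.5	1.0	5.8	2.4	0.8	1.4	4.3	4.0
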