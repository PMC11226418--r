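row	R2	R3	R4	R5	R6	R7	R8	R9	R10
Sum	2558	1401	516	2599	965	191	378	1954	1294
Average	142.1	77.8	28.7	144.4	53.6	10.6	21.0	108.6	71.9
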