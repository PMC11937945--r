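node	fiber_id
F01_01	2
F01_02	2
F01_03	2
F02_01	3
F02_02	3
F03_01	1
F03_02	1
F03_03	1
F03_04	1
F04_01	4
F04_02	4
G1	5
H1	6
R01	7
R02	8
R03	9
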