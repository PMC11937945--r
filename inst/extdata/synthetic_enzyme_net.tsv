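source	target	edge_type	multiplicity
G1	G1	fib_m	1
G1	H1	fib_m	1
H1	G1	fib_m	1
R01	F01_01	fib	1
R01	F01_02	fib	1
R01	F01_03	fib	1
R01	F03_01	fib	3
R01	F03_02	fib	3
R01	F03_03	fib	3
R01	F03_04	fib	3
R01	F04_01	fib	2
R01	F04_02	fib	2
R01	R01	reg	1
R02	F02_01	fib	2
R02	F02_02	fib	2
R02	F03_01	fib	3
R02	F03_02	fib	3
R02	F03_03	fib	3
R02	F03_04	fib	3
R02	F04_01	fib	2
R02	F04_02	fib	2
R02	R02	reg	2
R03	F04_01	fib	2
R03	F04_02	fib	2
R03	R03	reg	3
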