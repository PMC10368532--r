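id	chrom	pos	ref	alt	tumor_depth	tumor_alt	normal_depth	normal_alt
v01	chr1	1000	C	T	25	5	12	0
v02	chr1	2000	G	A	20	10	12	0
v03	chr2	3000	A	G	21	3	11	0
v04	chr2	4000	T	C	21	2	11	0
v05	chr3	5000	C	A	30	3	11	0
v06	chr3	6000	G	T	25	5	10	0
v07	chr4	7000	C	G	100	10	50	0
v08	chr4	8000	T	A	1000	99	50	0
v09	chr5	9000	A	T	10	5	100	6
v10	chr5	10000	G	C	9	5	100	0
v11	chr6	11000	C	T	100	5	100	7
v12	chr6	12000	T	G	100	5	100	6
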