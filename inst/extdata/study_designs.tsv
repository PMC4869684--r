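design	cohort	unit	n_units
1	1	NF2	250
1	2	NF2	250
1	3	NF2	250
1	4	NF2	250
1	5	NF2	250
2	1	NFv	250
2	2	NFv	250
2	3	NFv	250
2	4	NFv	250
2	5	NFv	250
3	1	NF2	100
3	2	NF2	175
3	3	U	400
3	4	U	700
3	5	U	1000
4	1	NFv	100
4	2	NFv	175
4	3	U	400
4	4	U	700
4	5	U	1000
5	1	NFv	100
5	2	NFv	175
5	3	NFv	250
5	4	NFv	325
5	5	NFv	400
6	1	NF2	250
6	2	NF2	250
6	3	NF2	250
6	4	NF2	250
6	5	NF2	250
6	6	U	1000
6	7	U	1000
6	8	U	1000
6	9	U	1000
6	10	U	1000
7	1	U	400
7	2	U	700
7	3	U	1000
7	4	U	1300
7	5	U	1600
7	6	U	400
7	7	U	700
7	8	U	1000
7	9	U	1300
7	10	U	1600
8	1	NF2	100
8	2	NF2	175
8	3	NF2	250
8	4	NF2	325
8	5	NF2	400
9	1	NF2	250
9	2	NF2	125
9	3	NF2	125
9	4	NF2	375
9	5	NF2	375
9	6	U	1000
9	7	U	500
9	8	U	500
9	9	U	1500
9	10	U	1500
10	1	NFv	250
10	2	NFv	250
10	3	NFv	250
10	4	NFv	250
10	5	NFv	250
10	6	NFv	250
10	7	NFv	250
10	8	U	1000
10	9	U	1000
10	10	U	1000
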