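# REBA worksheet Table C: Score A (rows) x Score B (columns).
# Transcribed from the published REBA employee assessment worksheet
# (Hignett & McAtamney 2000). Matrix format: row i = Score A = i,
# column j = Score B = j.
1	1	1	2	3	3	4	5	6	7	7	7
1	2	2	3	4	4	5	6	6	7	7	8
2	3	3	3	4	5	6	7	7	8	8	8
3	4	4	4	5	6	7	8	8	9	9	9
4	4	4	5	6	7	8	8	9	9	9	9
6	6	6	7	8	8	9	9	10	10	10	10
7	7	7	8	9	9	9	10	10	11	11	11
8	8	8	9	10	10	10	10	10	11	11	11
9	9	9	10	10	10	11	11	11	12	12	12
10	10	10	11	11	11	11	12	12	12	12	12
11	11	11	11	12	12	12	12	12	12	12	12
12	12	12	12	12	12	12	12	12	12	12	12
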