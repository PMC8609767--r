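chrom	start	end	n_a	n_b
1	10000000	110000000	1	2
3	5000000	85000000	1	2
7	65000000	145000000	1	2
11	2000000	50000000	1	2
2	100000000	200000000	0	1
5	60000000	160000000	0	1
13	25000000	105000000	0	1
17	30000000	78000000	0	1
4	60000000	140000000	2	2
8	50000000	130000000	2	2
20	32000000	62000000	2	2
9	55000000	125000000	0	2
22	18000000	50000000	0	2
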