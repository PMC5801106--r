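transcript_id	chrom	regulation	ratio
Os01t0372500	1	Up	25.2
Os01t0633500	1	Up	18.1
Os04t0662600	4	Up	36.0
Os06t0192100	6	Up	17.6
Os07t0217600	7	Down	0.01
Os09t0343200	9	Down	0.01
Os10t0395400	10	Up	27.7
Os11t0233201	11	Down	0.01
Os12t0222650	12	Up	25.3
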