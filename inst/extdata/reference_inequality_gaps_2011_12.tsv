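quintile	sex	gap_gbp
Q1	female	1127006663
Q1	male	1065236932
Q2	female	706629004
Q2	male	671287893
Q3	female	410841645
Q3	male	405654922
Q4	female	198794943
Q4	male	190121699
Q5	female	0
Q5	male	0
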