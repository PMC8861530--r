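marker_id	marker_type	genotypes	counts_S	counts_T
S1	A/G	GG:AG:AA	18:2:0	4:10:6
S2	A/G	GG:AG:AA	12:6:2	20:0:0
S3	A/G	GG:AG:AA	15:1:0	6:10:0
S4	T/C	CC:CT:TT	11:7:2	2:11:7
S5	A/G	GG:AG:AA	0:3:17	12:0:8
I4	Indel	In:Del:Indel	0:15:5	13:5:2
I8	Indel	In:Del:Indel	5:2:13	18:0:2
I9	Indel	In:Del:Indel	7:4:9	0:16:4
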