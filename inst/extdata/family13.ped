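SYNFAM1	I-1	0	0	1	2
SYNFAM1	I-2	0	0	2	1
SYNFAM1	II-1	I-1	I-2	2	1
SYNFAM1	II-2	I-1	I-2	1	2
SYNFAM1	II-3	I-1	I-2	2	2
SYNFAM1	II-5	I-1	I-2	1	2
SYNFAM1	II-6	0	0	2	0
SYNFAM1	II-7	I-1	I-2	1	1
SYNFAM1	II-9	I-1	I-2	2	1
SYNFAM1	III-1	II-5	II-6	1	2
SYNFAM1	III-2	II-5	II-6	2	1
SYNFAM1	III-3	II-5	II-6	1	2
SYNFAM1	III-4	II-5	II-6	2	1
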