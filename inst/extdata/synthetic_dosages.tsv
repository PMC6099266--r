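id	rs4588	rs116970203	rs4423214	rs10741657	rs6013897
S01	2	2	2	1	2
S02	1	2	1	0	2
S03	0	1	1	1	1
S04	1	2	2	2	2
S05	2	2	1	1	1
S06	1	2	2	1	2
S07	0	1	1	0	2
S08	2	2	1	2	1
S09	1	2	2	1	2
S10	1.5	2	1	1	1
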