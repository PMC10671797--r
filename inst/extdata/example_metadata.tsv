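sample	group
sample1	0
sample2	1
sample3	0
sample4	0
sample5	1
sample6	1
sample7	0
sample8	0
sample9	1
sample10	1
sample11	1
sample12	1
sample13	1
sample14	1
sample15	0
sample16	0
sample17	0
sample18	1
sample19	1
sample20	0
sample21	1
sample22	0
sample23	0
sample24	0
sample25	1
sample26	1
sample27	0
sample28	1
sample29	1
sample30	1
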