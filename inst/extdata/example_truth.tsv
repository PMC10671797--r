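taxon	gamma	alpha
taxon1	0	0
taxon2	0	0
taxon3	0	0
taxon4	0	0
taxon5	0	0
taxon6	0	0
taxon7	0	0
taxon8	0	0
taxon9	0	0
taxon10	1	1.636904
taxon11	0	0
taxon12	0	0
taxon13	0	0
taxon14	1	1.386294
taxon15	0	0
taxon16	0	0
taxon17	0	0
taxon18	0	0
taxon19	0	0
taxon20	0	0
taxon21	0	0
taxon22	0	0
taxon23	0	0
taxon24	0	0
taxon25	1	1.386294
taxon26	0	0
taxon27	0	0
taxon28	0	0
taxon29	0	0
taxon30	0	0
taxon31	1	2.261122
taxon32	0	0
taxon33	0	0
taxon34	0	0
taxon35	0	0
taxon36	0	0
taxon37	0	0
taxon38	0	0
taxon39	0	0
taxon40	0	0
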