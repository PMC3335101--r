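sample_id	cluster
s01	1
s02	1
s03	1
s04	1
s05	1
s06	1
s07	1
s08	1
s09	1
s10	1
s11	1
s12	1
s13	2
s14	2
s15	2
s16	2
s17	2
s18	2
s19	2
s20	2
s21	2
s22	2
s23	2
s24	2
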