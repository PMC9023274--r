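# MS2 (RefSeq NC_001417) gRNA stem-loops contacting the coat protein in the
# cryo-EM asymmetric reconstruction of the virion; 1-based inclusive.
102	114
179	200
593	606
902	915
977	990
1460	1470
1720	1731
1747	1763
1776	1791
2040	2053
2374	2387
2468	2481
2781	2796
2840	2852
3359	3372
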