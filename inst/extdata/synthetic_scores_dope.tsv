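design_id	score
design_01	1716
design_02	1754
design_03	1771
design_04	1839
design_05	1839
design_06	1902
design_07	1928
design_08	1960
design_09	2001
design_10	2044
design_11	2090
design_12	2133
design_13	2178
design_14	2223
design_15	2269
design_16	2310
design_17	2384
design_18	2458
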