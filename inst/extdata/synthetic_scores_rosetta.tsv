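design_id	score
design_01	-207
design_02	-262
design_03	-150
design_04	-199
design_05	-188
design_06	-170
design_08	-140
design_09	-120
design_10	-95
design_11	-80
design_12	-61
design_13	-44
design_14	-20
design_15	3
design_16	25
design_17	48
design_18	67
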