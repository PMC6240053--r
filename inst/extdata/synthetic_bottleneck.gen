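synthetic_bottleneck_species
L1
L2
L3
L4
L5
L6
L7
L8
L9
Pop
ind_1 , 101101 097100 100100 097103 098098 099100 097097 099099 101102
ind_2 , 101103 100100 100100 097097 098101 095095 097097 099099 100100
ind_3 , 101101 097100 100100 097097 098098 095100 097097 101101 101101
ind_4 , 100101 097100 100100 097103 098101 097097 097103 099101 101101
ind_5 , 101103 097100 100100 097102 098098 097100 097097 101101 102102
ind_6 , 101101 100100 100100 097097 099101 095099 097103 099101 101102
ind_7 , 101101 100100 100100 102103 098101 095099 097103 099101 100101
ind_8 , 101101 100100 100100 097102 098098 095100 097097 099099 101102
ind_9 , 101101 097100 100100 103103 098101 095099 097103 099099 101101
ind_10 , 100101 100100 100100 102103 098098 095099 097103 101101 100101
ind_11 , 101101 097097 100100 097103 099101 097097 097097 099101 101101
ind_12 , 101101 097100 100100 097102 098101 095100 097097 099099 100100
ind_13 , 101101 100100 100100 097102 098101 097097 097097 099101 101102
ind_14 , 101101 097097 100100 097097 098101 097100 097097 099101 100101
ind_15 , 100101 100100 100100 097103 099101 095095 097097 099101 101101
ind_16 , 101101 100100 100100 097103 098101 095097 097097 099101 101102
ind_17 , 101101 100100 100100 097102 098101 097097 097097 099101 101101
ind_18 , 100101 100100 100100 097097 098098 097097 097097 099099 100101
ind_19 , 101101 100100 100100 097103 098098 095097 097097 101101 100101
ind_20 , 101103 097100 100100 097102 101101 097100 097103 099101 100101
ind_21 , 101101 097097 100100 097097 098101 095095 097097 099099 102102
ind_22 , 101101 100100 100100 102102 098101 097097 103103 101101 100102
ind_23 , 101101 097097 100100 097097 098101 095100 097097 099099 101101
ind_24 , 101101 100100 100100 097103 098101 099099 097103 099101 100102
ind_25 , 101101 097100 100100 097102 098099 097097 097103 099099 100101
ind_26 , 101101 097100 100100 097102 098101 097100 097097 099099 100102
ind_27 , 100101 100100 100100 097097 098101 099100 097103 099099 101101
ind_28 , 101101 100100 100100 097102 098101 097099 097097 099101 100102
ind_29 , 101101 100100 100100 097102 099099 097100 097103 099101 100102
ind_30 , 101101 100100 100100 097097 098098 095097 097103 101101 102102
ind_31 , 101101 097097 100100 097102 101101 095097 097103 099101 101101
ind_32 , 101101 097100 100100 097102 101101 097097 097097 099101 101102
ind_33 , 100101 097100 100100 097097 101101 095099 097097 099099 101101
ind_34 , 101101 097100 100100 097097 098098 097097 097097 099099 100101
ind_35 , 101101 097100 100100 102103 098101 095099 097097 101101 100101
ind_36 , 101101 097100 100100 097103 098101 095100 097103 099099 101102
ind_37 , 101101 097100 100100 097097 098101 095100 097097 099101 101102
ind_38 , 101101 097100 100100 097097 098098 099100 097097 099101 100102
ind_39 , 100101 097100 100100 097097 101101 097097 097097 099099 101102
ind_40 , 101101 100100 100100 097097 098099 095099 097097 099101 101102
ind_41 , 101101 097100 100100 097097 098098 099100 097103 099101 102102
ind_42 , 101101 097100 100100 097102 099101 095095 097097 099099 100101
ind_43 , 101101 100100 100100 097097 098098 099099 097097 099101 100101
ind_44 , 101101 100100 100100 097102 101101 097099 097097 099099 100102
ind_45 , 101103 097100 100100 097102 098101 099100 097097 099101 101102
ind_46 , 101101 097100 100100 097102 098101 097100 097097 099101 101102
ind_47 , 100101 100100 100100 097097 098098 097097 097097 101101 101102
ind_48 , 101101 100100 100100 097097 098098 097100 097097 099099 100100
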