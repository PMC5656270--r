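meal,duration_s,mass_g,bites,chews,swallows
breakfast,24458,18565,1312,15247,2115
lunch,36398,24318,1488,26939,2827
dinner,35893,23514,1460,19815,3023
all,96749,66397,4260,62001,7965
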