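"frequency_khz","gain_db"
20,0
25,0
30,0
35,0
40,0
45,-2.5
50,-5
55,-7.5
60,-10
65,-12.5
70,-15
75,-17.5
80,-20
85,-22.5
90,-25
95,-27.5
100,-30
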