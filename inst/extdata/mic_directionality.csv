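"frequency_khz","angle_deg","gain_db"
20,0,0
20,22.5,-0.0761
20,45,-0.2929
20,67.5,-0.6173
20,90,-1
20,112.5,-1.3827
20,135,-1.7071
20,157.5,-1.9239
20,180,-2
30,0,0
30,22.5,-0.0952
30,45,-0.3661
30,67.5,-0.7716
30,90,-1.25
30,112.5,-1.7284
30,135,-2.1339
30,157.5,-2.4048
30,180,-2.5
40,0,0
40,22.5,-0.1142
40,45,-0.4393
40,67.5,-0.926
40,90,-1.5
40,112.5,-2.074
40,135,-2.5607
40,157.5,-2.8858
40,180,-3
50,0,0
50,22.5,-0.1332
50,45,-0.5126
50,67.5,-1.0803
50,90,-1.75
50,112.5,-2.4197
50,135,-2.9874
50,157.5,-3.3668
50,180,-3.5
60,0,0
60,22.5,-0.1522
60,45,-0.5858
60,67.5,-1.2346
60,90,-2
60,112.5,-2.7654
60,135,-3.4142
60,157.5,-3.8478
60,180,-4
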