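delta_eps,temp_c,ratio
1.3,0,12.9
1.3,10,11.8
1.3,20,10.8
1.3,30,10.0
2.4,0,106
2.4,10,90.2
2.4,20,77.4
2.4,30,67.0
4.0,0,2400
4.0,10,1820
4.0,20,1410
4.0,30,1110
8.0,0,5530000
8.0,10,3200000
8.0,20,1920000
8.0,30,1190000
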