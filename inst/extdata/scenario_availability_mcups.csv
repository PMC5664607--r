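crop,current,km_0,km_5,km_10,km_15,km_20
Total,84.9,43.6,63.5,86.3,110.1,138.0
Dates,2.4,3.4,4.1,4.8,5.5,5.8
Kiwis,1.6,2.7,3.8,5.1,6.5,8.0
Broccoli,42.8,6.0,6.8,8.2,11.8,15.4
Lima beans,,0.2,0.2,0.3,0.3,0.4
Sweet potatoes,11.7,23.0,37.0,51.9,64.6,78.0
Great Northern beans,5.9,7.2,8.7,10.3,11.0,11.7
Mushrooms,20.6,1.2,2.9,5.6,10.3,18.6
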