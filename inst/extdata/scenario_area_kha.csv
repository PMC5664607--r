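crop,current,km_0,km_5,km_10,km_15,km_20
Total,148.7,143.9,209.5,280.7,344.7,412.2
Dates,3.0,6.0,7.3,8.6,9.8,10.3
Kiwis,1.7,10.1,14.5,19.4,24.6,30.5
Broccoli,54.1,10.7,12.1,14.7,21.1,27.6
Lima beans,19.2,3.8,4.3,5.1,6.3,8.1
Sweet potatoes,43.6,82.7,133.9,188.7,235.3,284.5
Great Northern beans,26.6,30.6,37.1,43.8,46.8,49.7
Mushrooms,0.4,0.1,0.2,0.4,0.8,1.4
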