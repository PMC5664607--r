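crop,myplate_subgroup,counties,state,share_pct
Dates,fruit,Riverside,California,55
Kiwis,fruit,Tulare,California,35
Kiwis,fruit,Butte,California,24
Broccoli,dark green,Monterey,California,39
Broccoli,dark green,Santa Barbara,California,20
Lima beans,starchy,Sussex and Kent,Delaware,25
Sweet potatoes,red and orange,Johnston; Nash; Sampson; Wilson,North Carolina,27
Sweet potatoes,red and orange,Calhoun,Mississippi,12
Sweet potatoes,red and orange,Merced,California,11
Great Northern beans,beans and peas,Scotts Bluff; Box Butte; Morrill,Nebraska,70
Mushrooms,other,Chester,Pennsylvania,29
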