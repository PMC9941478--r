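condition,replicate,latency_s,censored
5,1,0.575498579927716,FALSE
5,2,6.38498886131009,FALSE
5,3,6.83644037985547,FALSE
5,4,18.4481467412827,FALSE
5,5,6.32510087611899,FALSE
5,6,0.265996088523787,FALSE
5,7,0.762214181238815,FALSE
5,8,2.38254921208356,FALSE
5,9,0.580181354163658,FALSE
5,10,0.704432138687434,FALSE
15,1,67.2759502649825,FALSE
15,2,15.6834539521986,FALSE
15,3,35.7632601632146,FALSE
15,4,3.18505340502209,FALSE
15,5,3.74898199389924,FALSE
15,6,12.0367840959822,FALSE
15,7,120,TRUE
15,8,18.7703081988593,FALSE
15,9,16.7229158935038,FALSE
15,10,1.52946425622054,FALSE
25,1,18.88381219341,FALSE
25,2,4.301012347527,FALSE
25,3,5.71868071324422,FALSE
25,4,77.2535223956845,FALSE
25,5,2.70338387619936,FALSE
25,6,2.8049614462543,FALSE
25,7,32.5352291563105,FALSE
25,8,39.4076213061566,FALSE
25,9,29.8810286362932,FALSE
25,10,36.1610562841568,FALSE
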