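time,observation
0,-0.28201456447706075
103.44827586206897,-0.69776630317504695
206.89655172413794,-0.1680009872725502
310.34482758620692,1.0313088190536834
413.79310344827587,0.90374366297788877
517.24137931034488,2.8801305547732299
620.68965517241384,-0.24512149483118639
724.13793103448279,1.9781084947898073
827.58620689655174,4.742305189996844
931.0344827586207,3.2273459350806473
1034.4827586206898,11.341336788433782
1137.9310344827586,10.966742934378281
1241.3793103448277,12.057018737548725
1344.8275862068965,15.544437507600051
1448.2758620689656,19.809866691437843
1551.7241379310344,26.268091183482994
1655.1724137931035,30.886892838022877
1758.6206896551726,35.708993348561727
1862.0689655172414,40.228191163825805
1965.5172413793105,45.163626328856601
2068.9655172413795,47.762994831728136
2172.4137931034484,52.782151875182393
2275.8620689655172,57.531256876172087
2379.3103448275861,60.924732899840258
2482.7586206896553,63.808700728953312
2586.2068965517242,72.171417812456781
2689.655172413793,66.731687499693521
2793.1034482758623,71.226192458449475
2896.5517241379312,72.587112184524742
3000,76.534083218140935
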