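"grey_level","ink_weight_mg","counts","activity_rel","elapsed_min"
0.1,0.31647,526,0.5,18.5
0.1,0.32293,954,1,33.3
0.1,0.31793,1719,2,41.2
0.1,0.31834,522,0.5,10.9
0.1,0.32101,840,1,44.9
0.2,0.54298,2997,2,40
0.2,0.54099,727,0.5,44.7
0.2,0.54487,1810,1,7
0.2,0.54801,3047,2,36.2
0.2,0.53517,659,0.5,48
0.3,0.77861,2664,1,4.5
0.3,0.77718,5039,2,12.2
0.3,0.75824,1201,0.5,21.8
0.3,0.77281,2077,1,38
0.3,0.76969,3875,2,53.9
0.4,1.01137,1336,0.5,55.2
0.4,0.99703,2658,1,42.7
0.4,1.01684,5237,2,48.4
0.4,1.03616,1677,0.5,19.7
0.4,1.02022,3037,1,25.7
0.5,1.27114,7313,2,29.5
0.5,1.27299,1632,0.5,48.7
0.5,1.28081,3244,1,52.9
0.5,1.27843,6855,2,43.5
0.5,1.25514,1797,0.5,30.5
0.6,1.56065,4197,1,41.3
0.6,1.5524,8388,2,40.8
0.6,1.53988,2175,0.5,33.3
0.6,1.55314,5111,1,14.4
0.6,1.54508,9355,2,24.5
0.7,1.84126,2513,0.5,33.9
0.7,1.83014,6201,1,5.2
0.7,1.82121,9436,2,48.4
0.7,1.84603,2828,0.5,19.4
0.7,1.82239,4858,1,46.1
0.8,2.12228,13290,2,18
0.8,2.20836,2729,0.5,57.4
0.8,2.18645,5589,1,52
0.8,2.174,12334,2,34.6
0.8,2.1175,2542,0.5,54.5
0.9,2.51014,8217,1,12.3
0.9,2.55165,17166,2,5.4
0.9,2.51667,3052,0.5,54.7
0.9,2.56013,6206,1,59.5
0.9,2.50122,17477,2,0.6
1,2.90995,3599,0.5,59.9
1,2.90269,9754,1,7.6
1,2.93484,14924,2,51.2
1,2.91476,4904,0.5,5.7
1,2.89527,7511,1,47.4
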