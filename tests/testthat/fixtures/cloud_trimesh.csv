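x,y,z
-6.539346,-19.486302,9.891755
8.499799,-8.824380,-1.993510
-36.073846,-17.647597,4.331762
11.910950,-0.179495,-16.455006
-7.102196,10.506326,-27.334139
24.095466,-4.571979,-16.100608
-20.789198,-22.583307,15.259494
-27.095741,-16.850237,2.038824
-24.258505,-23.107552,33.756545
-2.897036,-7.472974,42.975782
19.930116,11.528632,17.355150
11.354352,2.621285,-46.755175
13.001553,-2.781641,30.437694
19.954909,27.158621,-8.048210
9.113425,26.279636,-19.941490
-2.699750,-10.824919,3.977694
-1.626808,-6.977248,16.649580
10.333551,16.530940,13.175520
-26.308569,3.503807,-14.038897
31.271476,-1.553113,22.346244
13.343371,2.474642,-26.923589
-5.603557,7.909392,19.094026
34.856791,9.446088,41.806141
-7.323005,6.071867,-7.017371
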