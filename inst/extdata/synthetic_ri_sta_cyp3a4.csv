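substrate_um,inhibitor_um,replicate,velocity
0.2,0,1,3.3199602810193323
0.2,0,2,3.2197624984159545
0.2,0,3,3.1932909663226967
0.2,0.125,1,2.3097283949267924
0.2,0.125,2,2.1016982714871784
0.2,0.125,3,2.15338568998244
0.2,0.25,1,1.4705342752462751
0.2,0.25,2,1.5050745576854736
0.2,0.25,3,1.5388604887919042
0.2,0.5,1,0.9709985877333717
0.2,0.5,2,0.9997680291169878
0.2,0.5,3,1.0704254695640272
0.4,0,1,4.459662841574406
0.4,0,2,4.974659242993843
0.4,0,3,5.00379676720139
0.4,0.125,1,3.6352760608430947
0.4,0.125,2,3.6734927151930106
0.4,0.125,3,3.7536556220515185
0.4,0.25,1,2.685465194857262
0.4,0.25,2,2.6014542906404237
0.4,0.25,3,2.5793776201114507
0.4,0.5,1,1.8100792813925484
0.4,0.5,2,1.970394183386489
0.4,0.5,3,1.9027658017479698
0.8,0,1,7.406072048966948
0.8,0,2,7.338146935570436
0.8,0,3,6.849959574313991
0.8,0.125,1,4.996851169434853
0.8,0.125,2,5.32702114347949
0.8,0.125,3,5.38966906160796
0.8,0.25,1,4.316859735309482
0.8,0.25,2,4.039594849941661
0.8,0.25,3,4.595699590701196
0.8,0.5,1,3.0781565152549395
0.8,0.5,2,3.1069238289673233
0.8,0.5,3,3.1184039240240784
1.6,0,1,8.085834862413408
1.6,0,2,8.354015801897782
1.6,0,3,7.916672349393868
1.6,0.125,1,7.385537710476199
1.6,0.125,2,7.030464901498626
1.6,0.125,3,6.311003214753481
1.6,0.25,1,6.143317666774612
1.6,0.25,2,5.615173522441206
1.6,0.25,3,6.095570037758852
1.6,0.5,1,4.726170325365313
1.6,0.5,2,4.785043636640296
1.6,0.5,3,4.663177638013833
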