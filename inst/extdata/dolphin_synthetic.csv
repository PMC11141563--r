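station,d,S,C,label
0,0.0785065,0.00484062,0.246636,boundary
0.0168,0.113658,,,
0.0336,0.137824,,,
0.0504,0.158542,,,
0.0672,0.177146,,,
0.084,0.194234,,,
0.1008,0.210144,,,
0.1176,0.225089,,,
0.1344,0.239218,,,
0.1512,0.252637,,,
0.168,0.265427,0.0553326,0.833865,boundary
0.1872,0.279354,,,
0.2064,0.292614,,,
0.2256,0.305267,,,
0.2448,0.317358,,,
0.264,0.328927,,,
0.2832,0.340006,,,
0.3024,0.350623,,,
0.3216,0.360802,,,
0.3408,0.370562,,,
0.36,0.379921,0.113364,1.19356,boundary
0.3816,0.389991,,,
0.4032,0.399592,,,
0.4248,0.408744,,,
0.4464,0.41746,,,
0.468,0.425754,,,
0.4896,0.433639,,,
0.5112,0.441127,,,
0.5328,0.448226,,,
0.5544,0.454946,,,
0.576,0.461296,0.167128,1.44921,boundary
0.6,0.467928,,,
0.624,0.474122,,,
0.648,0.479889,,,
0.672,0.485236,,,
0.696,0.490173,,,
0.72,0.494706,,,
0.744,0.498844,,,
0.768,0.502592,,,
0.792,0.505958,,,
0.816,0.508948,0.20344,1.59891,boundary
0.84,0.511567,,,
0.864,0.513822,,,
0.888,0.515718,,,
0.912,0.517261,,,
0.936,0.518456,,,
0.96,0.519307,,,
0.984,0.51982,,,
1.008,0.52,,,
1.032,0.519851,,,
1.056,0.519378,0.211864,1.63167,boundary
1.08,0.518586,,,
1.104,0.517479,,,
1.128,0.516062,,,
1.152,0.514338,,,
1.176,0.512312,,,
1.2,0.509989,,,
1.224,0.507372,,,
1.248,0.504466,,,
1.272,0.501274,,,
1.296,0.4978,0.194626,1.56389,boundary
1.32,0.49405,,,
1.344,0.490025,,,
1.368,0.48573,,,
1.392,0.48117,,,
1.416,0.476347,,,
1.44,0.471265,,,
1.464,0.465928,,,
1.488,0.460339,,,
1.512,0.454502,,,
1.536,0.448421,0.157929,1.40876,boundary
1.5576,0.442741,,,
1.5792,0.436868,,,
1.6008,0.430804,,,
1.6224,0.424551,,,
1.644,0.418112,,,
1.6656,0.411489,,,
1.6872,0.404684,,,
1.7088,0.397698,,,
1.7304,0.390534,,,
1.752,0.383194,0.115326,1.20384,boundary
1.7712,0.376522,,,
1.7904,0.369713,,,
1.8096,0.362768,,,
1.8288,0.355688,,,
1.848,0.348474,,,
1.8672,0.341126,,,
1.8864,0.333645,,,
1.9056,0.326033,,,
1.9248,0.318288,,,
1.944,0.310411,0.0756773,0.975186,boundary
1.9608,0.303412,,,
1.9776,0.296311,,,
1.9944,0.289109,,,
2.0112,0.281806,,,
2.028,0.274401,,,
2.0448,0.266893,,,
2.0616,0.259282,,,
2.0784,0.251567,,,
2.0952,0.243746,,,
2.112,0.235817,0.0436759,0.740842,boundary
2.1264,0.228935,,,
2.1408,0.221971,,,
2.1552,0.214923,,,
2.1696,0.207791,,,
2.184,0.200571,,,
2.1984,0.193261,,,
2.2128,0.185859,,,
2.2272,0.178361,,,
2.2416,0.170764,,,
2.256,0.163062,0.0208832,0.512275,boundary
2.2704,0.155251,,,
2.2848,0.147325,,,
2.2992,0.139277,,,
2.3136,0.131097,,,
2.328,0.122777,,,
2.3424,0.114303,,,
2.3568,0.105661,,,
2.3712,0.096831,,,
2.3856,0.0877901,,,
2.4,0.0785065,0.00484062,0.246636,boundary
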