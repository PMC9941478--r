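condition,replicate,latency_s,censored
5,1,0.71668874239549,FALSE
5,2,1.54156430840801,FALSE
5,3,1.57296708320972,FALSE
5,4,2.33305043282296,FALSE
5,5,1.53735426653292,FALSE
5,6,0.427636008327952,FALSE
5,7,0.818570528458804,FALSE
5,8,1.1892619679682,FALSE
5,9,0.719699723762757,FALSE
5,10,0.790522646997124,FALSE
5,11,0.710134347991665,FALSE
5,12,0.409484908916056,FALSE
5,13,0.759593587554991,FALSE
5,14,0.629374012420629,FALSE
5,15,0.613827264329021,FALSE
5,16,2.54746242214303,FALSE
5,17,2.50084180545371,FALSE
5,18,0.339027207065374,FALSE
5,19,1.65937968131464,FALSE
5,20,2.38987426201191,FALSE
5,21,0.54897767608054,FALSE
5,22,4.53534996506754,FALSE
5,23,2.58586121101241,FALSE
5,24,1.69842064742575,FALSE
5,25,1.54630564666199,FALSE
10,1,10.0623596598388,FALSE
10,2,2.78169219363481,FALSE
10,3,5.61535436796603,FALSE
10,4,0.944746926799417,FALSE
10,5,1.04490882216947,FALSE
10,6,2.26668307539076,FALSE
10,7,17.543703263438,FALSE
10,8,3.21734272612568,FALSE
10,9,2.92840231336974,FALSE
10,10,0.590005834028125,FALSE
10,11,0.335994480783813,FALSE
10,12,0.918364780951643,FALSE
10,13,2.65339154493995,FALSE
10,14,8.09654639000009,FALSE
10,15,2.99861996683895,FALSE
10,16,1.69034236615194,FALSE
10,17,8.90205438071798,FALSE
10,18,1.15297707100604,FALSE
10,19,2.60993089512922,FALSE
10,20,10.5377269846381,FALSE
10,21,3.75660950702904,FALSE
10,22,1.37169399575659,FALSE
10,23,4.11914784570919,FALSE
10,24,12.105297161017,FALSE
10,25,12.7759707288187,FALSE
15,1,4.82905277032405,FALSE
15,2,1.11178362239152,FALSE
15,3,1.4689772258047,FALSE
15,4,19.7443729352123,FALSE
15,5,0.718993267441082,FALSE
15,6,0.743294509826228,FALSE
15,7,8.31742439511957,FALSE
15,8,10.0735395273152,FALSE
15,9,7.63919160580056,FALSE
15,10,9.24393873642924,FALSE
15,11,14.0233332609717,FALSE
15,12,22.00973419509,FALSE
15,13,2.2441494125725,FALSE
15,14,12.6893007198307,FALSE
15,15,1.1230845038533,FALSE
15,16,37.5368201784624,FALSE
15,17,8.30055542317944,FALSE
15,18,9.02201498092554,FALSE
15,19,12.6413986403454,FALSE
15,20,5.10128116858917,FALSE
15,21,15.4823557262247,FALSE
15,22,3.60845311312005,FALSE
15,23,2.62837122278288,FALSE
15,24,0.716829180362494,FALSE
15,25,4.4430100940662,FALSE
20,1,0.690338728064671,FALSE
20,2,9.84615171367056,FALSE
20,3,18.5140469780515,FALSE
20,4,1.44431922589943,FALSE
20,5,27.4194140469547,FALSE
20,6,27.1761084648348,FALSE
20,7,3.50125914365316,FALSE
20,8,5.44478893714023,FALSE
20,9,18.2408164937372,FALSE
20,10,4.30749429012649,FALSE
20,11,16.2805075165208,FALSE
20,12,12.7821424806652,FALSE
20,13,5.00612538000569,FALSE
20,14,6.01886824104004,FALSE
20,15,3.19561471333727,FALSE
20,16,2.74166344815725,FALSE
20,17,12.6052250365888,FALSE
20,18,8.48922749079518,FALSE
20,19,14.5853232601819,FALSE
20,20,14.6397128181694,FALSE
20,21,16.068425015765,FALSE
20,22,2.62204579607995,FALSE
20,23,14.5391477573825,FALSE
20,24,7.96309162842104,FALSE
20,25,2.27955396606567,FALSE
25,1,0.799036454083499,FALSE
25,2,21.7512995797133,FALSE
25,3,10.6141187903006,FALSE
25,4,6.57913401831825,FALSE
25,5,0.625657338863253,FALSE
25,6,28.0192443495464,FALSE
25,7,1.69582970356569,FALSE
25,8,13.2041208533494,FALSE
25,9,15.5208318243658,FALSE
25,10,10.8290919260122,FALSE
25,11,10.2542062403995,FALSE
25,12,26.2417145539882,FALSE
25,13,9.61710266810842,FALSE
25,14,32.3498345192369,FALSE
25,15,14.5259281806254,FALSE
25,16,7.39371186979115,FALSE
25,17,3.85245593907312,FALSE
25,18,1.7664769265359,FALSE
25,19,1.39418904769363,FALSE
25,20,6.05822387372151,FALSE
25,21,21.8975347408017,FALSE
25,22,18.4876041579915,FALSE
25,23,10.7129286094103,FALSE
25,24,6.25919832629152,FALSE
25,25,68.0535073631917,FALSE
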