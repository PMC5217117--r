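"temperature","replicate","transfer","count_A","count_B"
"15",1,2,2945,7055
"15",1,4,1333,8667
"15",1,6,602,9398
"15",2,2,2855,7145
"15",2,4,1421,8579
"15",2,6,601,9399
"15",3,2,2884,7116
"15",3,4,1387,8613
"15",3,6,597,9403
"15",4,2,2927,7073
"15",4,4,1421,8579
"15",4,6,625,9375
"15",5,2,2926,7074
"15",5,4,1453,8547
"15",5,6,628,9372
"15",6,2,2852,7148
"15",6,4,1388,8612
"15",6,6,663,9337
"15",7,2,2889,7111
"15",7,4,1391,8609
"15",7,6,633,9367
"15",8,2,2904,7096
"15",8,4,1372,8628
"15",8,6,630,9370
"15",9,2,2858,7142
"15",9,4,1373,8627
"15",9,6,624,9376
"25",1,2,1591,8409
"25",1,4,326,9674
"25",1,6,58,9942
"25",2,2,1640,8360
"25",2,4,343,9657
"25",2,6,72,9928
"25",3,2,1515,8485
"25",3,4,320,9680
"25",3,6,71,9929
"25",4,2,1571,8429
"25",4,4,349,9651
"25",4,6,72,9928
"25",5,2,1563,8437
"25",5,4,370,9630
"25",5,6,79,9921
"25",6,2,1618,8382
"25",6,4,358,9642
"25",6,6,87,9913
"25",7,2,1608,8392
"25",7,4,325,9675
"25",7,6,60,9940
"25",8,2,1684,8316
"25",8,4,328,9672
"25",8,6,62,9938
"25",9,2,1583,8417
"25",9,4,373,9627
"25",9,6,64,9936
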