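planted_hit_synthetic
 OpenBabel09252616013D

 53 52  0  0  0  0  0  0  0  0999 V2000
    2.4732    0.5230    2.8617 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.1877   -0.8037    2.1444 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3433   -1.9653    3.1357 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6826   -0.7735    1.7461 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0163   -0.9930    0.8260 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.5993   -0.8734    0.6913 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.8521   -0.9236   -0.8404 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.0891    0.4973    1.1761 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.3234   -2.0758    1.4040 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.8805   -2.3217    1.4216 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.5144   -2.3517    0.0271 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.5781   -1.1856    2.2196 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.2598   -3.6444    2.2231 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.8674   -5.1060    1.8172 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.4274   -5.5485    0.4537 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.5029   -6.0553    2.8729 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.3580   -5.3507    1.8492 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7494    0.7002    3.6666 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3992    1.3708    2.1724 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.4565    0.5248    3.3336 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.7693   -1.7719    4.0490 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.3729   -2.1199    3.4534 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.9696   -2.9031    2.7105 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0492   -0.5078    2.6026 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.3439   -1.7500    1.3827 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4866   -0.0373    0.9586 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6038   -0.2513    0.1238 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7274   -1.9667    0.4018 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.1964   -0.2268   -1.3769 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.6646   -1.9250   -1.2425 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.8682   -0.6277   -1.1066 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.3803    1.2906    0.9159 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.0342    0.7809    0.7029 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.2491    0.5147    2.2564 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.8579   -2.9646    0.9806 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.0369   -2.0473    2.4560 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.6934   -1.3431   -0.3586 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.8849   -2.8767   -0.6949 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.4941   -2.8426    0.0437 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.5918   -0.2393    1.6746 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.6328   -1.4252    2.4159 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.0896   -1.0193    3.1832 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.8990   -3.4960    3.2519 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.3580   -3.6481    2.3142 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.5229   -5.5354    0.4470 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.0708   -4.9256   -0.3656 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.1124   -6.5729    0.2198 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.5938   -6.0910    2.7846 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.1348   -7.0844    2.7604 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.2610   -5.7366    3.8966 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.8600   -4.9420    0.9676 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.9010   -4.9179    2.7484 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.1249   -6.4222    1.8468 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 18  1  0  0  0  0
  1 19  1  0  0  0  0
  1 20  1  0  0  0  0
  2  3  1  0  0  0  0
  2  4  1  0  0  0  0
  2  5  1  0  0  0  0
  3 21  1  0  0  0  0
  3 22  1  0  0  0  0
  3 23  1  0  0  0  0
  4 24  1  0  0  0  0
  4 25  1  0  0  0  0
  4 26  1  0  0  0  0
  5  6  1  0  0  0  0
  5 27  1  0  0  0  0
  5 28  1  0  0  0  0
  6  7  1  0  0  0  0
  6  8  1  0  0  0  0
  6  9  1  0  0  0  0
  7 29  1  0  0  0  0
  7 30  1  0  0  0  0
  7 31  1  0  0  0  0
  8 32  1  0  0  0  0
  8 33  1  0  0  0  0
  8 34  1  0  0  0  0
  9 10  1  0  0  0  0
  9 35  1  0  0  0  0
  9 36  1  0  0  0  0
 10 11  1  0  0  0  0
 10 12  1  0  0  0  0
 10 13  1  0  0  0  0
 11 37  1  0  0  0  0
 11 38  1  0  0  0  0
 11 39  1  0  0  0  0
 12 40  1  0  0  0  0
 12 41  1  0  0  0  0
 12 42  1  0  0  0  0
 13 14  1  0  0  0  0
 13 43  1  0  0  0  0
 13 44  1  0  0  0  0
 14 15  1  0  0  0  0
 14 16  1  0  0  0  0
 14 17  1  0  0  0  0
 15 45  1  0  0  0  0
 15 46  1  0  0  0  0
 15 47  1  0  0  0  0
 16 48  1  0  0  0  0
 16 49  1  0  0  0  0
 16 50  1  0  0  0  0
 17 51  1  0  0  0  0
 17 52  1  0  0  0  0
 17 53  1  0  0  0  0
M  END
$$$$
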