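cause,overall,male,female,young,middle,old
J18.9,0.28514949,0.2663358,0.31307550,0.303030,0.2550335,0.2861578
I61.9,0.8600605,0.8740831,0.83730158,0.285714,0.88851351,0.85574092
J98.4,0.14804722,0.1426710,0.1548254,0.1176470,0.122362,0.14930489
A41.9,0.01851851,0.016194331,0.02162162,0.1379310,0.0133333,0.01447368
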