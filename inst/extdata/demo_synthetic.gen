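synthetic two-ecotype demo (generated by the package simulator)
L01
L02
L03
L04
L05
L06
L07
L08
POP
sav1_1 ,  0205 0205 0202 0505 0506 0505 0303 0101
sav1_2 ,  0305 0101 0202 0505 0405 0102 0303 0101
sav1_3 ,  0505 0102 0202 0505 0406 0205 0303 0101
sav1_4 ,  0205 0102 0102 0505 0405 0205 0306 0101
sav1_5 ,  0505 0102 0202 0505 0406 0505 0103 0101
sav1_6 ,  0205 0202 0102 0505 0405 0105 0303 0101
sav1_7 ,  0505 0101 0101 0505 0506 0505 0303 0101
sav1_8 ,  0305 0105 0102 0505 0204 0505 0103 0101
sav1_9 ,  0305 0101 0102 0105 0205 0205 0103 0101
sav1_10 ,  0203 0102 0102 0505 0406 0505 0303 0101
POP
sav2_1 ,  0205 0202 0202 0505 0204 0505 0103 0101
sav2_2 ,  0205 0202 0103 0505 0404 0105 0303 0101
sav2_3 ,  0205 0102 0202 0505 0405 0505 0303 0101
sav2_4 ,  0505 0505 0202 0505 0405 0105 0303 0101
sav2_5 ,  0205 0105 0202 0505 0204 0505 0103 0101
sav2_6 ,  0205 0202 0202 0505 0204 0505 0103 0101
sav2_7 ,  0205 0102 0103 0506 0405 0505 0101 0101
sav2_8 ,  0505 0205 0202 0505 0405 0505 0303 0101
sav2_9 ,  0205 0105 0102 0505 0404 0505 0303 0101
sav2_10 ,  0205 0101 0202 0505 0506 0105 0103 0101
POP
for1_1 ,  0103 0105 0203 0505 0404 0505 0506 0606
for1_2 ,  0102 0405 0303 0505 0404 0404 0505 0606
for1_3 ,  0102 0404 0303 0505 0404 0505 0305 0202
for1_4 ,  0102 0506 0202 0505 0404 0505 0505 0606
for1_5 ,  0203 0404 0303 0505 0404 0404 0305 0206
for1_6 ,  0101 0204 0303 0305 0404 0405 0306 0206
for1_7 ,  0101 0104 0303 0505 0404 0505 0505 0606
for1_8 ,  0103 0104 0303 0405 0404 0405 0606 0106
for1_9 ,  0202 0306 0203 0305 0404 0505 0506 0202
for1_10 ,  0102 0404 0203 0505 0404 0405 0306 0606
POP
for2_1 ,  0103 0102 0103 0505 0404 0505 0506 0206
for2_2 ,  0303 0404 0303 0305 0406 0405 0506 0206
for2_3 ,  0103 0303 0103 0303 0404 0505 0505 0206
for2_4 ,  0303 0404 0204 0305 0404 0505 0506 0206
for2_5 ,  0101 0304 0104 0505 0406 0405 0506 0206
for2_6 ,  0102 0405 0104 0505 0406 0505 0506 0606
for2_7 ,  0203 0404 0203 0305 0404 0505 0306 0206
for2_8 ,  0103 0404 0101 0505 0404 0405 0506 0206
for2_9 ,  0203 0304 0103 0305 0404 0405 0506 0606
for2_10 ,  0102 0406 0203 0305 0404 0404 0505 0202
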