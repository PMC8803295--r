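individual,population,ecotype,latitude,longitude
sav1_1,sav1,savanna,-15.5,-47.2
sav1_2,sav1,savanna,-15.5,-47.2
sav1_3,sav1,savanna,-15.5,-47.2
sav1_4,sav1,savanna,-15.5,-47.2
sav1_5,sav1,savanna,-15.5,-47.2
sav1_6,sav1,savanna,-15.5,-47.2
sav1_7,sav1,savanna,-15.5,-47.2
sav1_8,sav1,savanna,-15.5,-47.2
sav1_9,sav1,savanna,-15.5,-47.2
sav1_10,sav1,savanna,-15.5,-47.2
sav2_1,sav2,savanna,-16.2,-46.1
sav2_2,sav2,savanna,-16.2,-46.1
sav2_3,sav2,savanna,-16.2,-46.1
sav2_4,sav2,savanna,-16.2,-46.1
sav2_5,sav2,savanna,-16.2,-46.1
sav2_6,sav2,savanna,-16.2,-46.1
sav2_7,sav2,savanna,-16.2,-46.1
sav2_8,sav2,savanna,-16.2,-46.1
sav2_9,sav2,savanna,-16.2,-46.1
sav2_10,sav2,savanna,-16.2,-46.1
for1_1,for1,forest,-19.1,-43.4
for1_2,for1,forest,-19.1,-43.4
for1_3,for1,forest,-19.1,-43.4
for1_4,for1,forest,-19.1,-43.4
for1_5,for1,forest,-19.1,-43.4
for1_6,for1,forest,-19.1,-43.4
for1_7,for1,forest,-19.1,-43.4
for1_8,for1,forest,-19.1,-43.4
for1_9,for1,forest,-19.1,-43.4
for1_10,for1,forest,-19.1,-43.4
for2_1,for2,forest,-20.3,-42
for2_2,for2,forest,-20.3,-42
for2_3,for2,forest,-20.3,-42
for2_4,for2,forest,-20.3,-42
for2_5,for2,forest,-20.3,-42
for2_6,for2,forest,-20.3,-42
for2_7,for2,forest,-20.3,-42
for2_8,for2,forest,-20.3,-42
for2_9,for2,forest,-20.3,-42
for2_10,for2,forest,-20.3,-42
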