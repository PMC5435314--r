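id,name,type,adjacency,module
1,Acetabulum,bone,2 8 20 22 27 28 29 30 31 40 41 44 45 48,Thigh
2,Adductor femoris,muscle,1 22,Thigh
3,Aponeurosis plantaris,connective_knot,10 11 12 13 14 23 24 33 50,Foot
4,Caudofemoralis,muscle,22 54,Hip
5,Coccygeoiliacus,muscle,28 54,Hip
6,Coccygeosacralis,muscle,46 54,Hip
7,Contrahentium caput longum,muscle,33 50,Shank
8,Cruralis,muscle,1 20 21 32,Thigh
9,Cruroastralagus,muscle,50 53,Shank
10,Digit I,bone,3 34,Foot
11,Digit II,bone,3 35,Foot
12,Digit III,bone,3 36,Foot
13,Digit IV,bone,3 37,Foot
14,Digit V,bone,3 38,Foot
15,Distal tarsal 1,bone,16 34 35 50,Foot
16,Distal tarsal 2-3,bone,15 23 35 36 37 50,Foot
17,Extensor cruris tibialis,muscle,22 53,Shank
18,Extensor digitorum longus,muscle,35 36 37 53,Foot
19,Extensor iliotibialis A,muscle,21 28,Hip
20,Extensor iliotibialis B,muscle,1 8 21,Thigh
21,Fascia latae,connective_knot,8 19 20 32,Thigh
22,Femur,bone,1 2 4 17 25 26 29 30 31 32 39 40 41 42 43 49 51,Thigh
23,Fibulare,bone,3 16 37 38 39 50 51 53,Foot
24,Flexor digitorum communis,muscle,3 25 26,Calf
25,Flexor digitorum communis ot Knot I,connective_knot,22 24 53,Calf
26,Flexor digitorum communis ot Knot II,connective_knot,22 24 53,Calf
27,Gracilis major et minor,muscle,1 53,Shank
28,Iliac Shaft,bone,1 5 19 42 43 46,Hip
29,Iliofemoralis,muscle,1 22,Thigh
30,Ischioflexorius,muscle,1 22,Thigh
31,Ischiotrochantericus B,muscle,1 22,Thigh
32,Knee Knot,connective_knot,8 21 22 49 53,Thigh
33,Ligamentum calcanei,connective_knot,3 7 53,Shank
34,Metatarsal I,bone,10 15,Foot
35,Metatarsal II,bone,11 15 16 18,Foot
36,Metatarsal III,bone,12 16 18,Foot
37,Metatarsal IV,bone,13 16 18 23,Foot
38,Metatarsal V,bone,14 23,Foot
39,Peroneus,muscle,22 23,Foot
40,Puboischiofemoralis externus A,muscle,1 22,Thigh
41,Puboischiofemoralis externus B,muscle,1 22,Thigh
42,Puboischiofemoralis internus A,muscle,22 28,Hip
43,Puboischiofemoralis internus B,muscle,22 28,Hip
44,Pubotibialis A,muscle,1 53,Shank
45,Pubotibialis B,muscle,1 53,Shank
46,Sacral vertebra,bone,6 28 54,Hip
47,Tarsalis anticus,muscle,50 53,Shank
48,Tenuissimus,muscle,1 49,Thigh
49,Tenuissimus it Knot,connective_knot,22 32 48 53,Thigh
50,Tibiale,bone,3 7 9 15 16 23 47 51 52 53,Shank
51,Tibialis anticus,muscle,22 23 50,Shank
52,Tibialis anticus brevis,muscle,50 53,Shank
53,Tibiofibula,bone,9 17 18 23 25 26 27 32 33 44 45 47 49 50 52,Shank
54,Urostyle,bone,4 5 6 46,Hip
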