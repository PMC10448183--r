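point,x,y,z
17,-62,-50,18
18,-50,-56,10
19,-37,-59,6
20,-25,-57,4
21,-14,-52,4
22,14,-52,4
23,25,-57,4
24,37,-59,6
25,50,-56,10
26,62,-50,18
27,0,-45,6
28,0,-33,0
29,0,-21,-5
30,0,-9,-10
31,-16,3,2
32,-8,6,-2
33,0,7,-4
34,8,6,-2
35,16,3,2
36,-45,-30,12
37,-38,-34,9
38,-27,-35,8
39,-20,-32,8
40,-27,-27,8
41,-38,-26,9
42,20,-32,8
43,27,-35,8
44,38,-34,9
45,45,-30,12
46,38,-26,9
47,27,-27,8
48,-25,32,8
49,-16,27,4
50,-7,25,2
51,0,26,1
52,7,25,2
53,16,27,4
54,25,32,8
55,16,40,5
56,7,43,3
57,0,44,2
58,-7,43,3
59,-16,40,5
60,-19,32,6
61,-7,31,2
62,0,31,1
63,7,31,2
64,19,32,6
65,7,34,2
66,0,34,1
67,-7,34,2
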