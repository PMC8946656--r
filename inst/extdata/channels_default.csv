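index,ex_center_nm,ex_halfwidth_nm,em_low_nm,em_high_nm,fluorophore_hint
1,340,5,380,410,none
2,340,5,406,436,none
3,340,5,433,463,elastin
4,340,5,459,489,none
5,340,5,485,515,none
6,340,5,512,542,none
7,340,5,538,568,none
8,340,5,565,595,none
9,340,5,591,621,none
10,340,5,617,647,none
11,340,5,644,674,none
12,340,5,670,700,lipopigment
13,365,5,405,435,none
14,365,5,429,459,none
15,365,5,453,483,none
16,365,5,477,507,none
17,365,5,501,531,none
18,365,5,525,555,none
19,365,5,550,580,none
20,365,5,574,604,none
21,365,5,598,628,none
22,365,5,622,652,none
23,365,5,646,676,none
24,365,5,670,700,none
25,390,5,430,460,none
26,390,5,452,482,none
27,390,5,474,504,none
28,390,5,495,525,none
29,390,5,517,547,none
30,390,5,539,569,flavins
31,390,5,561,591,none
32,390,5,583,613,none
33,390,5,605,635,none
34,390,5,626,656,none
35,390,5,648,678,none
36,390,5,670,700,none
37,420,5,460,490,none
38,420,5,479,509,none
39,420,5,498,528,none
40,420,5,517,547,none
41,420,5,536,566,none
42,420,5,555,585,none
43,420,5,575,605,none
44,420,5,594,624,none
45,420,5,613,643,none
46,420,5,632,662,none
47,420,5,651,681,none
48,420,5,670,700,none
49,450,5,490,520,none
50,450,5,508,538,none
51,450,5,526,556,none
52,450,5,544,574,PPIX
53,450,5,562,592,none
54,450,5,580,610,none
55,450,5,598,628,none
56,450,5,616,646,none
57,450,5,634,664,none
58,450,5,652,682,none
59,450,5,670,700,none
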