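profile_id,eddy_id,relation,zone,norm_radius,period
1,,unused,,,night
2,,unused,,,night
3,,unused,,,night
4,,unused,,,night
5,,unused,,,night
6,2,control,,,night
7,2,control,,,night
8,2,control,,,night
9,2,inside,intern,0.6988157286,night
10,2,inside,intern,0.349536207,night
13,2,inside,effective_border,0.7070634629,day
14,2,control,,,day
15,2,control,,,day
16,2,control,,,day
17,,unused,,,day
18,,unused,,,day
19,,unused,,,day
20,,unused,,,day
21,,unused,,,day
22,,unused,,,day
23,,unused,,,day
24,,unused,,,day
25,,unused,,,day
26,,unused,,,day
27,,unused,,,day
28,,unused,,,day
29,,unused,,,day
30,,unused,,,day
31,,unused,,,day
34,,unused,,,night
35,,unused,,,night
36,,unused,,,night
37,,unused,,,night
38,,unused,,,night
39,3,control,,,night
40,3,control,,,night
41,3,control,,,night
42,3,inside,effective_border,0.9424565638,night
43,3,inside,intern,0.6468039756,night
44,3,inside,intern,0.3513862922,night
45,3,inside,core,0.06314039366,night
48,3,inside,effective_border,0.8541205297,day
49,3,control,,,day
50,3,control,,,day
51,3,control,,,day
52,,unused,,,day
53,,unused,,,day
54,,unused,,,day
55,,unused,,,day
56,,unused,,,day
57,,unused,,,day
58,,unused,,,day
59,,unused,,,day
60,1,control,,,day
61,1,control,,,day
62,1,control,,,day
63,1,inside,effective_border,0.8170175923,day
64,1,inside,speed_border,0.4430850638,day
65,1,inside,core,0.07939450387,day
66,1,inside,intern,0.3061044031,day
69,1,control,,,night
70,1,control,,,night
71,,unused,,,night
72,,unused,,,night
73,,unused,,,night
74,,unused,,,night
75,,unused,,,night
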