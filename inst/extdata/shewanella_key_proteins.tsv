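rank	CS_0.4	CS_0.5	CS_0.6	CS_0.7	CS_0.8	CS_0.9
1	SO_1325	SO_1325	SO_1325	SO_1325	SO_1325	SO_0228
2	SO_3292	SO_3292	SO_3292	SO_3292	SO_0226	SO_1325
3	SO_0435	SO_3430	SO_1126	SO_3471	SO_1207	SO_2491
4	SO_3430	SO_3440	SO_3430	SO_3430	SO_2491	SO_0226
5	SO_3440	SO_1126	SO_3471	SO_3209	SO_3471	SO_0009
6	SO_1126	SO_0435	SO_0435	SO_1126	SO_3292	SO_1207
7	SO_3471	SO_3471	SO_3440	SO_0435	SO_1926	SO_2912
8	SO_2619	SO_2619	SO_2619	SO_2491	SO_3430	SO_3292
9	SO_3432	SO_3432	SO_1207	SO_1926	SO_2406	SO_0610
10	SO_4749	SO_4749	SO_3209	SO_3440	SO_1126	SO_1677
11	SO_1197	SO_1926	SO_1926	SO_4747	SO_0236	SO_3471
12	SO_0603	SO_4215	SO_4747	SO_0226	SO_0009	SO_0237
13	SO_2411	SO_4747	SO_3432	SO_4215	SO_0610	SO_3207
14	SO_1926	SO_0603	SO_4749	SO_4749	SO_3209	SO_4428
15	SO_4215	SO_0226	SO_3441	SO_1207	SO_0435	SO_3209
16	SO_3441	SO_3209	SO_4586	SO_3432	SO_2780	SO_2619
17	SO_1207	SO_0009	SO_0770	SO_2619	SO_0237	SO_1629
18	SO_4586	SO_1197	SO_0009	SO_4586	SO_4747	SO_3210
19	SO_4747	SO_1207	SO_4215	SO_0009	SO_0608	SO_0247
20	SO_3639	SO_3441	SO_0226	SO_0228	SO_0425	SO_3639
21	SO_0226	SO_4016	SO_0610	SO_2406	SO_2619	SO_3430
22	SO_1552	SO_4586	SO_1197	SO_0610	SO_1473	SO_0435
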