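druse_id,sd_low_octa,sd_low_oct,ss_low_octa,ss_low_oct
1,TRUE,TRUE,FALSE,FALSE
2,TRUE,TRUE,FALSE,FALSE
3,TRUE,TRUE,FALSE,FALSE
4,TRUE,TRUE,FALSE,FALSE
5,TRUE,TRUE,FALSE,FALSE
6,TRUE,TRUE,FALSE,FALSE
7,TRUE,TRUE,FALSE,FALSE
8,TRUE,TRUE,FALSE,FALSE
9,TRUE,TRUE,FALSE,FALSE
10,TRUE,TRUE,FALSE,FALSE
11,TRUE,TRUE,TRUE,FALSE
12,TRUE,TRUE,TRUE,FALSE
13,TRUE,TRUE,TRUE,FALSE
14,TRUE,TRUE,TRUE,FALSE
15,TRUE,FALSE,TRUE,FALSE
16,TRUE,FALSE,TRUE,FALSE
17,TRUE,FALSE,TRUE,FALSE
18,FALSE,FALSE,FALSE,FALSE
19,FALSE,FALSE,FALSE,FALSE
20,FALSE,FALSE,FALSE,FALSE
21,FALSE,FALSE,FALSE,FALSE
22,FALSE,FALSE,FALSE,FALSE
23,FALSE,FALSE,FALSE,FALSE
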