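bin,n,age_mean,age_sd,btv_mean,btv_sd,mgv_mean,mgv_sd,pbd_mean,pbd_sd
40-44,62,42,1,545,345,111,164,24,21
45-49,120,47,1,539,314,77,64,17,15
50-54,292,52,1,589,365,64,59,14,12
55-59,190,57,1,657,416,56,55,13,14
60-64,176,62,2,627,401,51,43,13,13
65-69,123,67,1,663,424,50,57,10,9
70-74,70,72,1,676,412,57,43,11,9
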