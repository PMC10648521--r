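region,btv_mean,btv_sd,share_btv_mean,share_btv_sd,mgv_mean,mgv_sd,share_mgv_mean,share_mgv_sd,pbd_mean,pbd_sd,pbd_ratio_mean,pbd_ratio_sd
Entire,614,388,NA,NA,62,68,NA,NA,14,13,NA,NA
UOQ,208,135,34,9,21,23,34,14,13,13,99,31
UIQ,164,107,28,8,13,15,21,11,11,13,75,27
LOQ,126,17,19,7,17,24,26,13,19,17,142,47
LIQ,117,12,19,7,12,17,18,10,13,14,92,37
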