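window_len_s,mean_nni,sdnn,sdsd,rmssd,median_nni,cvsd,mean_hr,min_hr,max_nni
5,0.9096,-0.0089,0.3678,0.5448,0.8963,-0.2537,0.9100,0.6410,0.6301
10,0.9350,0.2859,0.5741,0.5848,0.9272,0.5637,0.9363,0.7518,0.7576
20,0.9516,0.4887,0.8060,0.8074,0.9476,0.7174,0.9521,0.8250,0.8387
30,0.9606,0.5890,0.8468,0.8473,0.9582,0.7731,0.9610,0.8587,0.8731
40,0.9674,0.6472,0.8616,0.8619,0.9649,0.7823,0.9676,0.8798,0.8934
50,0.9723,0.6940,0.8623,0.8624,0.9705,0.7878,0.9722,0.8956,0.9080
60,0.9759,0.7330,0.8830,0.8831,0.9745,0.8081,0.9755,0.9079,0.9187
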