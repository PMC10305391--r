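model,5s,10s,20s,30s,40s,50s,60s
extra_trees,0.6390,0.7589,0.9036,0.9480,0.9723,0.9816,0.9962
gradient_boosting,0.6892,0.7606,0.8484,0.8905,0.9290,0.9600,0.9850
knn,0.6284,0.7403,0.8783,0.9286,0.9635,0.9759,0.9933
linear,0.6305,0.7056,0.7740,0.8189,0.8705,0.9172,0.9475
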