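# Example end-to-end pipeline configuration (flat key = value format).
# A synthetic feature table is generated because neither 'images' nor
# 'features' is set; point 'images' at a with_locust/without_locust
# directory tree to run on real data.
backbone = tinycnn
selector = abc+svc
classifiers = lr,svm
split = 0.8
folds = 5
seed = 11
synth_n = 200
synth_d = 20
synth_k = 3
synth_effect = 2
abc_colony = 10
abc_limit = 5
abc_iters = 25
abc_lambda = 0.01
out = locustsel_run
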