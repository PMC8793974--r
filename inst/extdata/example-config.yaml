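# Example wsvm run configuration: a quick end-to-end smoke run on a
# synthetic dataset with the Cleveland-like default structure.
# The full published protocol corresponds to ratios
# [0.95, 0.90, 0.80, 0.75, 0.50] with n_iter: 1000 and tune: true.
data:
  synthetic:
    n: 297
    seed: 11
weights_mode: per_split
standardize: true
tune: false
cost: 1
ratios: [0.8]
n_iter: 5
master_seed: 1
methods: [wsvm, svm]
out_dir: wsvm-results
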