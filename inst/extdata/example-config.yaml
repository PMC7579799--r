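# Minimal pipeline configuration: analyse a generated scenario with
# nominal thresholds.  Point `data:` at a wide CSV (and describe the
# instrument) to analyse real responses instead; set
# `thresholds: montecarlo` with `nrep: 1000` for empirical thresholds.
scenario: one_uniform
thresholds: analytic
alpha: 0.01
seed: 1
out_dir: difdyad-results
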