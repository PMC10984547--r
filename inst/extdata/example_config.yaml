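# example configuration for run_full()
seed: 7
out_dir: langbias-results
sr_fixture: true
simulate_metaepi:
  K: 14
  seed: 7
tau2: reml
assoc_method: firth
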