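# Fast smoke-test run: balanced 2-site, 6-accession design, 3 traits.
seed: 1
n_boot: 200
out_dir: qstfst_tiny
mating_system: selfing
fdr_alpha: 0.05
simulate:
  fixture: tiny
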