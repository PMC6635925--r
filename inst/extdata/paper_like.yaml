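# Full-scale demonstration run: simulated dataset with the study's
# dimensions (12 + 13 sites, 31 + 33 accessions, 2 selfed offspring each,
# 61 genotyped individuals, Fst 0.44, Table-1-like trait panel).
seed: 1
n_boot: 1000
out_dir: qstfst_paper_like
mating_system: selfing
fdr_alpha: 0.05
simulate:
  fixture: paper_like
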