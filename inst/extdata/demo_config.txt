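# Demo configuration: a desk-scale synthetic study small enough to run in
# seconds. All analysis parameters keep their defaults (150 bp windows,
# 1 kb promoters, 10% change at adjusted p < 0.05, top 10 genes).
seed: 11
n_chroms: 1
chrom_length: 1000000
n_genes: 100
reads_per_sample: 40000
out_dir: hmeseq_demo
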