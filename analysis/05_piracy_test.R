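#!/usr/bin/env Rscript

# Stage 5: the quantitative molecular-piracy verdict on both benchmarks.
# Proviral copies (host records nearly identical to a viral record, the
# EsK1/Kesv situation) are excluded automatically before the test.

library(porephylo)

for (scen in c("independent", "piracy")) {
  aln <- read_alignment_fasta(file.path("results", paste0("alignment_", scen, ".fasta")))
  labs <- read_label_map(file.path("results/benchmarks", scen, "labels.tsv"))
  v <- run_piracy_test(aln, labs, methods = c("nj", "parsimony"), seed = 1)
  print(v)
  write_verdict_json(v, file.path("results", paste0("verdict_", scen, ".json")))
}
cat("verdict reports written under results/\n")
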