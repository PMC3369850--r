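#!/usr/bin/env Rscript

# Stage 3: progressive multiple alignment of the pore modules and the
# alignment statistics (pairwise identity/similarity) that motivated the
# whole exercise: the viral channels are far from their hosts yet retain
# the channel architecture.

library(porephylo)

for (scen in c("independent", "piracy")) {
  labs <- read_label_map(file.path("results/benchmarks", scen, "labels.tsv"))
  mods <- read_fasta(file.path("results", paste0("pore_modules_", scen, ".fasta")))
  mods <- assign_roles(mods, labs)
  aln <- align_progressive(mods)
  write_alignment_fasta(aln, file.path("results", paste0("alignment_", scen, ".fasta")))
  st <- pairwise_stats_matrix(aln)
  write.table(round(st$identity, 2),
              file.path("results", paste0("identity_", scen, ".tsv")),
              sep = "\t", quote = FALSE)
  viral <- labs$id[labs$role == "viral"]
  host <- labs$id[labs$role == "host"]
  vv <- st$identity[viral, viral][upper.tri(diag(length(viral)))]
  vh <- st$identity[viral, host]
  cat(sprintf("%-12s %d columns; identity within viral %.1f%%, viral-host %.1f%%\n",
              scen, ncol(aln), mean(vv), mean(vh)))
}
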