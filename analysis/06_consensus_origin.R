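#!/usr/bin/env Rscript

# Stage 6: the ancestor-hunt workflow - derive the viral pore-module
# consensus, search it against a candidate protein set containing channel
# and non-channel decoys, and check the best hits for the canonical
# selectivity filter. A hit similar in its membrane topology but lacking
# the canonical filter (the LPA situation) is reported as a probable
# non-channel.

library(porephylo)

labs <- read_label_map("results/benchmarks/independent/labels.tsv")
mods <- read_fasta("results/pore_modules_independent.fasta")
mods <- assign_roles(mods, labs)
viral_mods <- mods[mods$role == "viral", ]

cons <- viral_consensus(viral_mods, threshold = 0.7)
write_fasta(seq_records("viral_consensus", gsub("X", "A", cons$sequence),
                        desc = sprintf("threshold %.2f over %d modules",
                                       cons$threshold, length(cons$ids))),
            "results/viral_consensus.fasta")
cat("consensus:", cons$sequence, "\n")

# candidate set: one true host channel, one filter-ablated decoy, one
# soluble protein
host1 <- mods[mods$role == "host", ][1, ]
decoy <- host1
hit <- scan_filter_motifs(decoy$seq)
if (nrow(hit)) {
  p <- hit$position[[1]]
  substr(decoy$seq, p - 5, p + 2) <- "DKESNQRD"
}
decoy$id <- "decoy_no_filter"
soluble <- seq_records("soluble", paste(rep("DKESNQRD", 10), collapse = ""))
pool <- rbind(host1, decoy,
              soluble[, c("id", "seq", "alphabet", "role", "source", "desc")])

ranked <- search_local(gsub("X", "A", cons$sequence), pool)
print(ranked)

evals <- lapply(setNames(pool$seq, pool$id), evaluate_hit)
write_hit_report(evals, "results/hit_evaluation.tsv")
for (id in names(evals)) {
  cat(sprintf("%-16s canonical filter: %-5s TMs: %d\n", id,
              evals[[id]]$has_canonical_filter, evals[[id]]$tm_count))
}
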