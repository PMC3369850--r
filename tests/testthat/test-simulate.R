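test_that("scenario trees have the configured structure", {
  cfg <- scenario_config("independent", seed = 3)
  tr <- simulate_tree(cfg)
  viral <- tr$labels$id[tr$labels$role == "viral"]
  expect_equal(length(viral), cfg$n_viral)
  expect_equal(sum(tr$labels$role == "host"),
               cfg$n_host_species * cfg$n_paralogs_per_host)
  expect_true(is_monophyletic(tr$tree, viral))

  cfg2 <- scenario_config("piracy", seed = 3)
  tr2 <- simulate_tree(cfg2)
  viral2 <- tr2$labels$id[tr2$labels$role == "viral"]
  expect_true(is_monophyletic(tr2$tree, viral2))
  # nested: the smallest clade containing a viral taxon plus a non-viral one
  # is host-pure and from the attachment species
  clade <- porephylo:::smallest_mixed_clade(tr2$tree, viral2[[1]], viral2)
  hosts_in <- setdiff(clade, viral2)
  expect_gte(length(hosts_in), 1L)
  own <- unique(tr2$labels$source[tr2$labels$role == "viral"])
  expect_equal(length(own), 1L)
  expect_true(all(sub("_K[0-9]+$", "", hosts_in) == own))

  expect_identical(write_newick(simulate_tree(cfg)$tree),
                   write_newick(simulate_tree(cfg)$tree))
  expect_error(scenario_config("independent", viral_divergence_depth = 0.01),
               "independent scenario needs")
  expect_error(scenario_config("piracy", viral_divergence_depth = 2),
               "piracy scenario needs")
})

test_that("sequences evolve along the tree with conserved architecture", {
  cfg <- scenario_config("independent", seed = 4)
  tr <- simulate_tree(cfg)
  # zero-length branches: all leaves identical to each other
  tr0 <- tr
  tr0$tree$edge.length[] <- 0
  sim0 <- evolve_sequences(tr0, cfg)
  expect_equal(length(unique(sim0$records$seq)), 1L)
  expect_equal(sum(sim0$truth$branch_changes$changes), 0L)

  sim <- evolve_sequences(tr, cfg)
  expect_equal(sort(sim$records$id), sort(tr$tree$tip.label))
  # planted coordinates point at real features
  for (i in seq_len(nrow(sim$truth$coords))) {
    co <- sim$truth$coords[i, ]
    s <- sim$records$seq[[match(co$id, sim$records$id)]]
    expect_equal(co$filter_end - co$filter_start + 1L,
                 nchar(cfg$architecture$filter))
    expect_equal(co$tm1_end - co$tm1_start + 1L, cfg$architecture$tm1_len)
  }
})

test_that("an absolutely conserved filter is detected in every leaf", {
  for (s in 1:5) {
    b <- simulate_benchmark(scenario_config("independent", seed = 700 + s,
                                            filter_rate = 0))
    for (i in seq_len(nrow(b$records))) {
      hits <- scan_filter_motifs(b$records$seq[[i]])
      co <- b$truth$coords[b$truth$coords$id == b$records$id[[i]], ]
      expect_true(any(hits$canonical & hits$position == co$filter_start + 5L),
                  info = b$records$id[[i]])
    }
  }
})

test_that("pairwise identity tracks divergence depth (calibration)", {
  # two lineages, 1.5 substitutions/site each from the ancestor: identity in
  # the 20-30% band the viral alignment statistics motivate
  cfg <- scenario_config("independent", seed = 11, indel_rate = 0)
  ids <- c()
  for (s in 1:10) {
    cfg$seed <- 800 + s
    tr <- list(tree = read_newick("(va:1.5,vb:1.5,vc:1.5);"),
               labels = data.frame(id = c("va", "vb", "vc"),
                                   role = "viral", source = "spA",
                                   stringsAsFactors = FALSE))
    sim <- evolve_sequences(tr, cfg)
    aln <- aln_matrix(setNames(sim$records$seq, sim$records$id))
    st <- pairwise_stats_matrix(aln)
    ids <- c(ids, st$identity[upper.tri(st$identity)])
  }
  expect_gt(mean(ids), 20)
  expect_lt(mean(ids), 30)

  # identity decreases monotonically with depth
  mean_ident_at <- function(depth) {
    out <- c()
    for (s in 1:6) {
      cfg$seed <- 900 + s
      tr <- list(tree = read_newick(sprintf("(va:%g,vb:%g,vc:%g);",
                                            depth, depth, depth)),
                 labels = data.frame(id = c("va", "vb", "vc"),
                                     role = "viral", source = "spA",
                                     stringsAsFactors = FALSE))
      sim <- evolve_sequences(tr, cfg)
      aln <- aln_matrix(setNames(sim$records$seq, sim$records$id))
      st <- pairwise_stats_matrix(aln)
      out <- c(out, mean(st$identity[upper.tri(st$identity)]))
    }
    mean(out)
  }
  depths <- c(0.05, 0.3, 1.0, 2.0)
  curve <- vapply(depths, mean_ident_at, numeric(1))
  expect_true(all(diff(curve) < 0))
})

test_that("emitted viral leaves pass the candidate screen at default noise", {
  passed <- c()
  for (s in 1:40) {
    b <- simulate_benchmark(scenario_config("independent", seed = 1000 + s))
    vir <- b$records[b$records$role == "viral", ]
    scr <- screen_candidates(vir)
    passed <- c(passed, vapply(scr, `[[`, logical(1), "passed"))
  }
  expect_gte(length(passed), 200L)
  expect_gte(mean(passed), 0.95)
})

test_that("benchmark directories are complete and byte-reproducible", {
  cfg <- scenario_config("piracy", seed = 12)
  d1 <- file.path(withr::local_tempdir(), "bench1")
  d2 <- file.path(withr::local_tempdir(), "bench2")
  make_benchmark(cfg, d1)
  make_benchmark(cfg, d2)
  files <- c("sequences.fasta", "labels.tsv", "truth.nwk", "truth.json",
             "README.txt")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_error(make_benchmark(cfg, d1), "not empty")
  expect_silent(suppressMessages(make_benchmark(cfg, d1, force = TRUE)))

  # the fixture round-trips through the standard readers consistently
  recs <- read_fasta(file.path(d1, "sequences.fasta"))
  labs <- read_label_map(file.path(d1, "labels.tsv"))
  expect_setequal(recs$id, labs$id)
  tru <- read_newick(file.path(d1, "truth.nwk"))
  expect_setequal(tru$tip.label, recs$id)
  viral <- labs$id[labs$role == "viral"]
  expect_true(is_monophyletic(tru, viral))
})
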