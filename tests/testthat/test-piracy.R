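test_that("monophyly is an exact bipartition test on unrooted trees", {
  t1 <- read_newick("((v1,v2),(h1,h2));")
  expect_true(is_monophyletic(t1, c("v1", "v2")))
  t2 <- read_newick("((v1,h1),(v2,h2));")
  expect_false(is_monophyletic(t2, c("v1", "v2")))
  # trivial sets are always monophyletic
  expect_true(is_monophyletic(t2, "v1"))
  expect_true(is_monophyletic(t2, c("v1", "h1", "h2")))
  expect_error(is_monophyletic(t1, c("v1", "zz")), "unknown id: zz")
})

test_that("monophyly agrees with an independent clade enumeration", {
  set.seed(61)
  for (i in 1:20) {
    tr <- random_topology(paste0("x", 1:8))
    taxa <- sample(tr$tip.label, sample(2:6, 1))
    # oracle via ape::prop.part on the rooted representation: a set is
    # monophyletic on the unrooted tree iff it or its complement is a clade
    pp <- ape::prop.part(tr)
    clades <- lapply(pp, function(ix) sort(attr(pp, "labels")[ix]))
    comp <- sort(setdiff(tr$tip.label, taxa))
    oracle <- length(taxa) <= 1 || length(comp) <= 1 ||
      any(vapply(clades, identical, logical(1), sort(taxa))) ||
      any(vapply(clades, identical, logical(1), comp))
    expect_equal(is_monophyletic(tr, taxa), oracle, info = paste("case", i))
  }
})

test_that("monophyly is invariant to leaf order and re-serialization", {
  set.seed(62)
  tr <- random_topology(paste0("x", 1:8))
  taxa <- c("x2", "x5", "x7")
  base <- is_monophyletic(tr, taxa)
  expect_equal(is_monophyletic(read_newick(write_newick(tr)), taxa), base)
  rot <- ape::rotateConstr(tr, sample(tr$tip.label))
  expect_equal(is_monophyletic(rot, sample(taxa)), base)
})

test_that("clade support looks up the exact bipartition", {
  report <- data.frame(split = c("d|e", "b|c"), support = c(88, 12),
                       stringsAsFactors = FALSE)
  ids <- c("a", "b", "c", "d", "e")
  expect_equal(clade_support(report, c("d", "e"), ids), 88)
  expect_equal(clade_support(report, c("a", "b", "c"), ids), 88) # complement
  expect_equal(clade_support(report, c("c", "d"), ids), 0)       # absent
  expect_equal(clade_support(report, "a", ids), 100)             # trivial
})

test_that("proviral copies are excluded by identity threshold", {
  labels <- data.frame(id = c("V1", "V2", "H1", "H2"),
                       role = c("viral", "viral", "host", "host"),
                       stringsAsFactors = FALSE)
  idm <- matrix(40, 4, 4, dimnames = list(labels$id, labels$id))
  diag(idm) <- 100
  idm["V1", "H1"] <- idm["H1", "V1"] <- 99
  expect_equal(suppressMessages(proviral_exclusion(labels, idm, 95)), "H1")
  expect_equal(proviral_exclusion(labels, idm, 100), character()) # strict
  idm["V1", "H1"] <- idm["H1", "V1"] <- 40
  expect_equal(proviral_exclusion(labels, idm, 95), character())
})

test_that("the piracy test reads both scenarios correctly and is seed-stable", {
  b <- simulate_benchmark(scenario_config("independent", seed = 5))
  aln <- align_progressive(prepare_pore_modules(b$records))
  v1 <- suppressMessages(run_piracy_test(aln, b$truth$labels, methods = "nj",
                                         seed = 1))
  expect_s3_class(v1, "piracy_verdict")
  expect_equal(v1$verdict, "independent-clade")
  expect_true(v1$per_method$nj$viral_monophyletic)
  expect_gte(v1$per_method$nj$viral_clade_support, 95)
  v1b <- suppressMessages(run_piracy_test(aln, b$truth$labels, methods = "nj",
                                          seed = 1))
  expect_equal(v1$per_method$nj$viral_clade_support,
               v1b$per_method$nj$viral_clade_support)

  b2 <- simulate_benchmark(scenario_config("piracy", seed = 5))
  aln2 <- align_progressive(prepare_pore_modules(b2$records))
  v2 <- suppressMessages(run_piracy_test(aln2, b2$truth$labels, methods = "nj",
                                         seed = 1))
  expect_equal(v2$verdict, "host-nested")
  expect_error(suppressMessages(
    run_piracy_test(aln[1:3, ], b$truth$labels, methods = "nj")), ">= 2")
})

test_that("label shuffling destroys the independent-clade verdict", {
  n_indep <- 0L
  for (s in 1:8) {
    b <- simulate_benchmark(scenario_config("independent", seed = 400 + s))
    aln <- align_progressive(prepare_pore_modules(b$records))
    labs <- b$truth$labels
    perm <- porephylo:::with_seed(s, sample(nrow(labs)))
    labs$role <- labs$role[perm]
    labs$source <- labs$source[perm]
    v <- suppressMessages(tryCatch(
      run_piracy_test(aln, labs, methods = "nj", seed = 1),
      error = function(e) list(verdict = "error")))
    if (identical(v$verdict, "independent-clade")) n_indep <- n_indep + 1L
  }
  expect_lte(n_indep / 8, 0.05 + 1e-9)
})

test_that("verdicts serialize to JSON with full per-method evidence", {
  b <- simulate_benchmark(scenario_config("independent", seed = 6))
  aln <- align_progressive(prepare_pore_modules(b$records))
  v <- suppressMessages(run_piracy_test(aln, b$truth$labels, methods = "nj",
                                        seed = 1))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_verdict_json(v, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(back$verdict, v$verdict)
  expect_true("nj" %in% names(back$per_method))
  expect_equal(back$per_method$nj$viral_clade_support,
               v$per_method$nj$viral_clade_support)
})
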