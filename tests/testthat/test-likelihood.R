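test_that("JC69 two-taxon likelihood has the right analytic limits", {
  mod <- subst_model("JC69-nucleotide")
  aln <- aln_matrix(c(a = "A", b = "A"))
  near0 <- read_newick("(a:0.0000001,b:0.0000001);")
  expect_equal(exp(log_likelihood(near0, aln, mod)), 0.25, tolerance = 1e-5)
  far <- read_newick("(a:60,b:60);")
  expect_equal(exp(log_likelihood(far, aln, mod)), 0.0625, tolerance = 1e-6)
  # mismatched site at t -> infinity also approaches pi_i * pi_j
  expect_equal(exp(log_likelihood(far, aln_matrix(c(a = "A", b = "G")), mod)),
               0.0625, tolerance = 1e-6)
})

test_that("pruning equals brute-force ancestral summation (with gaps, gamma)", {
  set.seed(31)
  tr5 <- random_topology(paste0("t", 1:5))
  tr5$edge.length <- runif(nrow(tr5$edge), 0.05, 0.6)
  m <- matrix(sample(c("A", "C", "G", "T", "-"), 5 * 10, TRUE,
                     prob = c(0.22, 0.22, 0.22, 0.22, 0.12)), 5, 10,
              dimnames = list(paste0("t", 1:5), NULL))
  jc <- subst_model("JC69-nucleotide")
  expect_equal(log_likelihood(tr5, m, jc), log_likelihood_bruteforce(tr5, m, jc),
               tolerance = 1e-10)
  jcg <- subst_model("JC69-nucleotide", gamma_shape = 0.6)
  expect_equal(log_likelihood(tr5, m, jcg), log_likelihood_bruteforce(tr5, m, jcg),
               tolerance = 1e-10)

  tr4 <- random_topology(paste0("t", 1:4))
  tr4$edge.length <- runif(nrow(tr4$edge), 0.05, 0.4)
  mp <- matrix(sample(c(rownames(load_blosum62()), "X"), 4 * 6, TRUE), 4, 6,
               dimnames = list(paste0("t", 1:4), NULL))
  wag <- subst_model("empirical-protein")
  expect_equal(log_likelihood(tr4, mp, wag),
               log_likelihood_bruteforce(tr4, mp, wag), tolerance = 1e-10)
})

test_that("likelihood agrees with phangorn and is root-invariant", {
  skip_if_not_installed("phangorn")
  set.seed(32)
  tr <- random_topology(paste0("t", 1:6))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  m <- matrix(sample(rownames(load_blosum62()), 6 * 40, TRUE), 6, 40,
              dimnames = list(paste0("t", 1:6), NULL))
  wag <- subst_model("empirical-protein")
  ref <- phangorn::pml(tr, phangorn::phyDat(m, type = "AA"), model = "WAG")
  expect_equal(log_likelihood(tr, m, wag), ref$logLik, tolerance = 1e-6)

  # unrooted models do not care where the traversal is rooted
  for (mod in list(wag, subst_model("JC69-nucleotide"))) {
    aln <- if (mod$kind == "empirical-protein") m else sim_alignment(tr, 30, mod)
    base <- log_likelihood(tr, aln, mod)
    for (tip in c("t2", "t5")) {
      rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
      expect_equal(log_likelihood(rr, aln, mod), base, tolerance = 1e-8)
    }
  }
})

test_that("discrete gamma rates match the standard discretization", {
  skip_if_not_installed("phangorn")
  for (shape in c(0.3, 0.8, 2.5)) {
    expect_equal(discrete_gamma_rates(shape, 4),
                 phangorn::discrete.gamma(shape, 4), tolerance = 1e-10)
  }
  expect_equal(mean(discrete_gamma_rates(0.5, 4)), 1, tolerance = 1e-12)
})

test_that("ML search recovers the generating topology and branch lengths", {
  set.seed(33)
  tr <- read_newick("((a:0.12,b:0.25):0.08,(c:0.18,d:0.3):0.06,e:0.4);")
  mod <- subst_model("JC69-nucleotide")
  aln <- sim_alignment(tr, 500, mod)
  fit <- ml_search(aln, mod, seed = 1)
  expect_equal(rf_distance(fit$tree, tr), 0)
  # recovered lengths track the truth (25% + small floor covers the
  # sampling error of 500-site estimates)
  est <- sort(fit$tree$edge.length); tru <- sort(tr$edge.length)
  expect_true(all(abs(est - tru) <= pmax(0.25 * tru, 0.03)))
  # and match phangorn's optimized lengths on the same topology closely
  skip_if_not_installed("phangorn")
  pfit <- phangorn::optim.pml(
    phangorn::pml(fit$tree, phangorn::phyDat(aln, type = "DNA"), model = "JC"),
    optEdge = TRUE, control = phangorn::pml.control(trace = 0))
  expect_equal(fit$log_likelihood, pfit$logLik, tolerance = 1e-4)
  expect_equal(sort(fit$tree$edge.length), sort(pfit$tree$edge.length),
               tolerance = 0.01)
})

test_that("4-taxon ML search matches exhaustive topology comparison", {
  set.seed(34)
  tr <- ape::unroot(read_newick("((a:0.2,b:0.2):0.15,(c:0.2,d:0.2):0.001);"))
  mod <- subst_model("JC69-nucleotide")
  aln <- sim_alignment(tr, 300, mod)
  fit <- ml_search(aln, mod, seed = 1)
  enc <- porephylo:::likelihood_encode(aln, mod)
  lls <- vapply(enumerate_topologies(c("a", "b", "c", "d")), function(t0) {
    t0 <- porephylo:::optimize_branch_lengths(t0, enc, mod)
    porephylo:::ll_encoded(t0, enc, mod)
  }, numeric(1))
  expect_equal(fit$log_likelihood, max(lls), tolerance = 1e-4)
})

test_that("the degenerate all-identical alignment pins the analytic value", {
  aln <- aln_matrix(c(a = strrep("A", 10), b = strrep("A", 10),
                      c = strrep("A", 10), d = strrep("A", 10)))
  mod <- subst_model("JC69-nucleotide")
  fit <- ml_search(aln, mod, seed = 1)
  expect_equal(fit$log_likelihood, 10 * log(0.25), tolerance = 1e-4)
  expect_true(all(fit$tree$edge.length < 1e-3))
})

test_that("model construction is internally consistent", {
  wag <- subst_model("empirical-protein")
  expect_equal(sum(wag$freq), 1, tolerance = 1e-8)
  expect_equal(rowSums(wag$Q), rep(0, 20), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(-sum(wag$freq * diag(wag$Q)), 1, tolerance = 1e-10)
  P <- transition_prob(wag, 0.37)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(P >= 0))
  # stationarity: pi P = pi
  expect_equal(as.numeric(wag$freq %*% P), unname(wag$freq), tolerance = 1e-10)
  expect_error(subst_model("empirical-protein", gamma_shape = -1), "> 0")
})
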