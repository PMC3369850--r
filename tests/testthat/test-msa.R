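test_that("global pairwise alignment is optimal (enumeration oracle)", {
  a <- align_pair_global("GYG", "GYG")
  expect_equal(a$score, 19) # 6 + 7 + 6 on the BLOSUM62 diagonal
  expect_equal(unname(aln_strings(a$aln)), c("GYG", "GYG"))

  S <- porephylo:::resolve_matrix("BLOSUM62")
  b <- align_pair_global("AAA", "AA")
  expect_equal(b$score, 2 * 4 - 10) # two matches + one opened gap
  expect_equal(b$score, enumerate_global_score("AAA", "AA", S, -10, -1))

  set.seed(7)
  for (i in 1:20) {
    x <- paste(sample(rownames(load_blosum62()), sample(2:5, 1), TRUE), collapse = "")
    y <- paste(sample(rownames(load_blosum62()), sample(1:5, 1), TRUE), collapse = "")
    res <- align_pair_global(x, y)
    expect_equal(res$score, enumerate_global_score(x, y, S, -10, -1),
                 info = paste(x, y))
    # emitted alignment re-scores to the reported optimum
    expect_equal(score_alignment(res$aln), res$score, info = paste(x, y))
  }
  expect_error(align_pair_global("", "AA"), "empty")
})

test_that("pairwise scores agree with Biostrings on random sequences", {
  skip_if_not_installed("Biostrings")
  set.seed(8)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (i in 1:10) {
    x <- paste(sample(AA20 <- rownames(load_blosum62()), 12, TRUE), collapse = "")
    y <- paste(sample(AA20, 10, TRUE), collapse = "")
    mine <- align_pair_global(x, y)$score
    # Biostrings charges opening + extension for a gap's first position
    ref <- Biostrings::pairwiseAlignment(x, y, substitutionMatrix = BLOSUM62,
                                         gapOpening = 9, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(mine, ref, info = paste(x, y))
  }
})

test_that("progressive alignment preserves sequences and places gaps", {
  r <- seq_records(c("a", "b"), c("MTTVGYG", "MTTVGYG"))
  expect_false(any(align_progressive(r) == "-"))

  r3 <- seq_records(c("s1", "s2", "s3"), c("ACDEFG", "ACEFG", "ACDEFG"))
  aln <- aln_strings(align_progressive(r3))
  expect_equal(unname(aln), c("ACDEFG", "AC-EFG", "ACDEFG"))

  b <- simulate_benchmark(scenario_config("independent", seed = 4))
  v <- b$records[b$records$role == "viral", ]
  aln2 <- align_progressive(v)
  expect_equal(rownames(aln2), v$id) # row order = input order
  expect_equal(unname(degap(aln_strings(aln2))), v$seq)
  expect_error(align_progressive(v[1, ]), ">= 2")
})

test_that("identity and similarity statistics follow pairwise deletion", {
  aln <- aln_matrix(c(a = "GYG", b = "GYG"))
  st <- pairwise_stats(aln, 1, 2)
  expect_equal(st$identity_percent, 100)
  expect_equal(st$similarity_percent, 100)

  st2 <- pairwise_stats(aln_matrix(c(a = "GYG", b = "GFG")), "a", "b")
  expect_equal(st2$identity_percent, 200 / 3)
  expect_equal(st2$similarity_percent, 100) # BLOSUM62 Y/F = 3 > 0

  # gap and X columns drop out of the denominator
  st3 <- pairwise_stats(aln_matrix(c(a = "G-XAG", b = "GYAAG")), 1, 2)
  expect_equal(st3$columns_compared, 3L)
  expect_equal(st3$identity_percent, 100)

  expect_error(pairwise_stats(aln_matrix(c(a = "--A", b = "GG-")), 1, 2),
               "no comparable columns")

  # symmetry
  aln4 <- aln_matrix(c(a = "GYGLV", b = "GAGIV"))
  expect_equal(pairwise_stats(aln4, 1, 2), pairwise_stats(aln4, 2, 1))
  expect_equal(st2$identity_percent,
               pairwise_stats_matrix(aln_matrix(c(a = "GYG", b = "GFG")))$identity["a", "b"])
})

test_that("consensus follows majority, threshold and tie rules", {
  aln <- aln_matrix(c(a = "GGGG", b = "GGGG", c = "GGGA", d = "GGAA"))
  cs <- consensus_sequence(aln, 0.7)
  # col1 GGGG -> G; col2 GGGG -> G; col3 GGGA -> G (0.75 >= 0.7);
  # col4 GGAA -> X (tie)
  expect_equal(cs$sequence, "GGGX")
  # mostly-gap columns are dropped
  aln2 <- aln_matrix(c(a = "G-A", b = "G-A", c = "G-A", d = "GCA"))
  expect_equal(consensus_sequence(aln2, 0.7)$sequence, "GA")
  # threshold 1.0 on identical rows reproduces the sequence
  aln3 <- aln_matrix(c(a = "MTTVGYG", b = "MTTVGYG", c = "MTTVGYG"))
  expect_equal(consensus_sequence(aln3, 1.0)$sequence, "MTTVGYG")
  expect_error(consensus_sequence(aln[1, , drop = FALSE]), ">= 2")
  expect_error(consensus_sequence(aln, 0), "threshold")
})

test_that("local search ranks targets by Smith-Waterman score", {
  targets <- seq_records(c("self", "junk"), c("MTTVGYGLLF", "AAAA"))
  res <- search_local("MTTVGYGLLF", targets)
  expect_equal(res$target[[1]], "self")
  expect_equal(res$score[[1]], align_pair_global("MTTVGYGLLF", "MTTVGYGLLF")$score)
  expect_equal(res[res$target == "junk", "score"], 0)
  # G/A and Y/A score <= 0 in BLOSUM62, so no positive local path exists
  res2 <- search_local("GYGGYG", seq_records("t", "AAAA"))
  expect_equal(res2$score, 0)
  expect_true(all(res2[, c("q_start", "t_start")] == 0))
  # local score of an identical full-length pair equals the global score
  expect_error(search_local("GYG", seq_records("t", "AAA")[0, ]), "empty")
})

test_that("a family consensus retrieves its own family by local search", {
  hits_first <- 0L
  for (s in 1:20) {
    b <- simulate_benchmark(scenario_config("independent", seed = 300 + s))
    fam <- b$records[b$records$role == "viral", ]
    cons <- viral_consensus(fam, threshold = 0.5)
    decoys <- seq_records(paste0("d", 1:3),
                          vapply(1:3, function(i) {
                            paste(sample(rownames(load_blosum62()), 80, TRUE),
                                  collapse = "")
                          }, character(1)))
    pool <- rbind(fam[1, c("id", "seq", "alphabet", "role", "source", "desc")],
                  decoys)
    ranked <- search_local(gsub("X", "A", cons$sequence), pool)
    if (ranked$target[[1]] == fam$id[[1]]) hits_first <- hits_first + 1L
  }
  expect_gte(hits_first / 20, 0.95)
})
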