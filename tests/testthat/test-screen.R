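test_that("filter-motif scan finds all tripeptides with canonical context", {
  hits <- scan_filter_motifs("AATMTTVGYGDL")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "GYG")
  expect_equal(hits$position, 8L)
  expect_true(hits$canonical) # TMTTVGYG matches T..T.G[FY]G
  expect_equal(nrow(scan_filter_motifs("AAAAA")), 0L)
  h2 <- scan_filter_motifs("GYGAAGFG")
  expect_equal(h2$position, c(1L, 6L))
  expect_equal(h2$motif, c("GYG", "GFG"))
  expect_false(any(h2$canonical))
  # overlapping motifs are all reported
  expect_equal(scan_filter_motifs("GYGYG")$position, c(1L, 3L))
  # GLG can never be canonical
  h3 <- scan_filter_motifs("ATTTTAGLGA")
  expect_false(any(h3$canonical))
  expect_error(scan_filter_motifs(seq_records("n1", "ACGT", alphabet = "nucleotide")),
               "protein")
})

test_that("hydropathy profile is a sliding Kyte-Doolittle mean", {
  p <- hydropathy_profile(strrep("I", 21), 19)
  expect_equal(p$values, rep(4.5, 3))
  expect_equal(hydropathy_profile(strrep("R", 21), 19)$values, rep(-4.5, 3))
  # alternating sequence vs direct window sums
  s <- paste(rep(c("I", "R"), 10), collapse = "")
  p2 <- hydropathy_profile(s, 7)
  kd <- load_kd_scale()
  vals <- kd[strsplit(s, "")[[1]]]
  expected <- vapply(seq_len(nchar(s) - 6L), function(i) mean(vals[i:(i + 6L)]),
                     numeric(1))
  expect_equal(p2$values, unname(expected))
  # X contributes zero
  p3 <- hydropathy_profile(paste0(strrep("I", 9), "X", strrep("I", 9)), 19)
  expect_equal(p3$values, 18 * 4.5 / 19)
  expect_error(hydropathy_profile("IIIIIIII", 9), "longer than sequence")
  expect_error(hydropathy_profile(strrep("I", 30), 8), "odd")
})

test_that("consensus TM prediction matches direct window evaluation", {
  s <- paste0(strrep("D", 20), strrep("I", 30), strrep("D", 20))
  seg <- predict_tm_segments(s)
  expect_equal(nrow(seg), 1L)
  # brute-force: for each window size, mark residues covered by any window
  # whose mean is >= threshold
  kd <- load_kd_scale(); vals <- kd[strsplit(s, "")[[1]]]
  covered <- rep(FALSE, nchar(s))
  for (w in c(19, 21)) {
    for (i in seq_len(nchar(s) - w + 1L)) {
      if (mean(vals[i:(i + w - 1L)]) >= 1.6) covered[i:(i + w - 1L)] <- TRUE
    }
  }
  expect_equal(seg$start, min(which(covered)))
  expect_equal(seg$end, max(which(covered)))
  expect_true(seg$start <= 21 && seg$end >= 50) # covers the planted run
  expect_equal(seg$votes, 2L)

  expect_equal(nrow(predict_tm_segments(strrep("D", 60))), 0L)

  s2 <- paste0(strrep("L", 25), strrep("E", 30), strrep("L", 25))
  expect_equal(nrow(predict_tm_segments(s2)), 2L)
})

test_that("TM prediction responds monotonically to threshold and votes", {
  # raising the threshold can split one merged segment into two, so the
  # segment COUNT is not monotone; the residue coverage is, and so is the
  # vote rule
  coverage <- function(seg) if (nrow(seg)) sum(seg$end - seg$start + 1L) else 0L
  for (rep in 1:10) {
    b <- simulate_benchmark(scenario_config("independent", seed = rep))
    s <- b$records$seq[[1]]
    cov <- vapply(c(1.2, 1.6, 2.4), function(th) {
      coverage(predict_tm_segments(s, threshold = th))
    }, numeric(1))
    expect_true(all(diff(cov) <= 0), info = paste("seed", rep))
    n_v1 <- nrow(predict_tm_segments(s, min_votes = 1))
    n_v2 <- nrow(predict_tm_segments(s, min_votes = 2))
    expect_gte(n_v1, n_v2)
  }
})

test_that("candidate screen requires a motif plus two TM segments", {
  b <- simulate_benchmark(scenario_config("independent", seed = 2,
                                          filter_rate = 0))
  scr <- screen_candidates(b$records[b$records$role == "viral", ][1:2, ])
  expect_true(all(vapply(scr, `[[`, logical(1), "passed")))
  scr2 <- screen_candidates(seq_records(c("sol", "mem"),
                                        c(soluble_gyg, two_tm_no_motif)))
  expect_false(scr2$sol$passed)   # motif, no TMs
  expect_gte(nrow(scr2$sol$hits), 1L)
  expect_false(scr2$mem$passed)   # 2 TMs, no motif
  expect_equal(nrow(scr2$mem$tms), 2L)
  expect_equal(nrow(scr2$mem$hits), 0L)
  # report covers every record
  expect_equal(screen_summary(scr2)$id, c("sol", "mem"))
})

test_that("pore-module extraction recovers planted boundaries", {
  n_ok <- 0L; n_leaves <- 0L; n_extracted <- 0L
  for (s in 1:15) {
    b <- simulate_benchmark(scenario_config("independent", seed = 100 + s))
    mods <- prepare_pore_modules(b$records)
    tru <- b$truth$coords[match(mods$id, b$truth$coords$id), ]
    n_leaves <- n_leaves + nrow(mods)
    ok <- mods$is_module &
      abs(mods$module_start - tru$module_start) <= 21 / 2 &
      abs(mods$module_end - tru$module_end) <= 21 / 2
    n_extracted <- n_extracted + sum(mods$is_module)
    n_ok <- n_ok + sum(ok, na.rm = TRUE)
  }
  expect_gte(n_leaves, 200L)
  expect_gte(n_ok / n_leaves, 0.95)
})

test_that("extracted pore modules satisfy their ordering invariants", {
  for (s in 1:5) {
    b <- simulate_benchmark(scenario_config("piracy", seed = 200 + s))
    scr <- screen_candidates(b$records)
    for (x in scr) {
      mod <- tryCatch(extract_pore_module(x$record, x$tms, x$hits),
                      error = function(e) NULL)
      if (is.null(mod)) next
      p <- mod$filter$position
      expect_lte(mod$tm1$end, p - 1L)
      expect_gte(mod$tm2$start, p + 3L)
      expect_equal(mod$module_start, mod$tm1$start)
      expect_equal(mod$module_end, mod$tm2$end)
      expect_true(all(mod$pore_helix_aromatics >= p - 15 &
                      mod$pore_helix_aromatics < p))
      expect_equal(mod$seq,
                   substring(x$record$seq, mod$module_start, mod$module_end))
    }
  }
})

test_that("module extraction fails cleanly without a flanking TM pair", {
  # motif N-terminal of every TM
  s <- paste0("AAGYGAA", strrep("I", 22), strrep("DE", 13), strrep("L", 22))
  hits <- scan_filter_motifs(s)
  tms <- predict_tm_segments(s)
  expect_gte(nrow(tms), 2L)
  expect_error(extract_pore_module(s, tms, hits), "NoPoreModule")
  expect_error(extract_pore_module(s, tms[0, ], hits), "NoPoreModule")
  expect_error(extract_pore_module(s, tms, hits[0, ]), "NoPoreModule")
})

test_that("screening and extraction are deterministic", {
  b <- simulate_benchmark(scenario_config("independent", seed = 3))
  m1 <- prepare_pore_modules(b$records)
  m2 <- prepare_pore_modules(b$records)
  expect_identical(m1, m2)
})
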