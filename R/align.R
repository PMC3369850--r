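# Pairwise and progressive multiple alignment, alignment statistics,
# consensus sequences, and local-alignment search.
#
# Alignments are character matrices (rows = sequences, columns = alignment
# columns, rownames = ids, gap = "-"). Scores use a substitution matrix
# (bundled BLOSUM62 by default) with affine gaps: a gap of length k costs
# gap_open + (k - 1) * gap_extend (both scores <= 0).

resolve_matrix <- function(matrix) {
  if (is.character(matrix)) {
    if (toupper(matrix) != "BLOSUM62") stop("unknown matrix: ", matrix)
    matrix <- load_blosum62()
  }
  # X (unknown) scores 0 against everything
  if (!"X" %in% rownames(matrix)) {
    matrix <- rbind(cbind(matrix, X = 0), X = 0)
  }
  matrix
}

#' Alignment container helpers
#'
#' `aln_matrix()` converts gapped sequence strings (or a record
#' `data.frame`) into the package's alignment representation, a character
#' matrix with one row per sequence; `aln_strings()` is the inverse;
#' `degap()` removes gaps from one row. `read_alignment_fasta()` /
#' `write_alignment_fasta()` exchange aligned (gapped) FASTA.
#'
#' @param x named character vector of gapped strings, or a record
#'   `data.frame` with gapped `seq`.
#' @param aln an alignment character matrix.
#' @param path FASTA path.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return see individual descriptions.
#' @export
aln_matrix <- function(x) {
  if (is.data.frame(x)) x <- setNames(x$seq, x$id)
  lens <- nchar(x)
  if (length(unique(lens)) != 1L) stop("alignment rows have unequal length")
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  m
}

#' @rdname aln_matrix
#' @export
aln_strings <- function(aln) {
  setNames(apply(aln, 1L, paste, collapse = ""), rownames(aln))
}

#' @rdname aln_matrix
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' @rdname aln_matrix
#' @export
read_alignment_fasta <- function(path, alphabet = "protein") {
  recs <- read_fasta(path, alphabet = alphabet, gapped = TRUE)
  aln_matrix(recs)
}

#' @rdname aln_matrix
#' @export
write_alignment_fasta <- function(aln, path) {
  s <- aln_strings(aln)
  recs <- seq_records(names(s), s, gapped = TRUE)
  write_fasta(recs, path)
}

encode_seq <- function(seq, alphabet_order) {
  match(strsplit(seq, "")[[1]], alphabet_order)
}

# column frequency profile (residues x columns); gaps contribute nothing and
# the denominator is the total number of rows, so gappy columns carry less
# weight in profile-profile scores
profile_of <- function(aln, alphabet_order) {
  n <- nrow(aln)
  prof <- matrix(0, length(alphabet_order), ncol(aln),
                 dimnames = list(alphabet_order, NULL))
  for (i in seq_len(n)) {
    idx <- match(aln[i, ], alphabet_order)
    keep <- !is.na(idx)
    prof[cbind(idx[keep], which(keep))] <-
      prof[cbind(idx[keep], which(keep))] + 1 / n
  }
  prof
}

#' Optimal global pairwise alignment (affine gaps)
#'
#' Needleman-Wunsch-Gotoh dynamic programming. The reported score is the
#' optimum under the affine gap model and equals the score recomputed from
#' the emitted alignment with [score_alignment()].
#'
#' @param a,b one-row record `data.frame`s or plain sequence strings (same
#'   alphabet).
#' @param matrix substitution matrix name (`"BLOSUM62"`) or a numeric
#'   matrix with residue dimnames.
#' @param gap_open,gap_extend gap scores, `gap_open <= gap_extend <= 0`.
#' @return list with `aln` (2-row alignment matrix) and `score`.
#' @export
align_pair_global <- function(a, b, matrix = "BLOSUM62",
                              gap_open = -10, gap_extend = -1) {
  a <- as_named_seq(a, "seq_a"); b <- as_named_seq(b, "seq_b")
  if (!nzchar(a$seq) || !nzchar(b$seq)) stop("empty sequence")
  if (gap_open > gap_extend || gap_extend > 0) {
    stop("need gap_open <= gap_extend <= 0")
  }
  S <- resolve_matrix(matrix)
  ca <- strsplit(a$seq, "")[[1]]; cb <- strsplit(b$seq, "")[[1]]
  if (!all(ca %in% rownames(S))) stop("sequence a has residues outside the matrix")
  if (!all(cb %in% rownames(S))) stop("sequence b has residues outside the matrix")
  colScore <- S[ca, cb, drop = FALSE]
  dp <- .gotoh_dp(colScore, gap_open, gap_extend)
  rows <- moves_to_rows(dp$moves, ca, cb)
  aln <- rbind(rows$a, rows$b)
  rownames(aln) <- c(a$id, b$id)
  list(aln = aln, score = dp$score)
}

as_named_seq <- function(x, fallback) {
  if (is.data.frame(x)) list(id = x$id, seq = toupper(x$seq))
  else list(id = fallback, seq = toupper(x))
}

moves_to_rows <- function(moves, ca, cb) {
  n <- length(moves)
  ra <- character(n); rb <- character(n)
  i <- 0L; j <- 0L
  for (k in seq_len(n)) {
    if (moves[[k]] == 0L) {
      i <- i + 1L; j <- j + 1L; ra[[k]] <- ca[[i]]; rb[[k]] <- cb[[j]]
    } else if (moves[[k]] == 1L) {
      i <- i + 1L; ra[[k]] <- ca[[i]]; rb[[k]] <- "-"
    } else {
      j <- j + 1L; ra[[k]] <- "-"; rb[[k]] <- cb[[j]]
    }
  }
  list(a = ra, b = rb)
}

#' Recompute an alignment's affine-gap score
#'
#' @param aln a 2-row alignment matrix.
#' @inheritParams align_pair_global
#' @return numeric score.
#' @export
score_alignment <- function(aln, matrix = "BLOSUM62",
                            gap_open = -10, gap_extend = -1) {
  stopifnot(nrow(aln) == 2L)
  S <- resolve_matrix(matrix)
  score <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_len(ncol(aln))) {
    x <- aln[1L, k]; y <- aln[2L, k]
    if (x == "-" && y == "-") next
    if (x == "-") {
      score <- score + if (in_gap_a) gap_extend else gap_open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (y == "-") {
      score <- score + if (in_gap_b) gap_extend else gap_open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      score <- score + S[x, y]
      in_gap_a <- FALSE; in_gap_b <- FALSE
    }
  }
  score
}

# characters excluded from identity/distance denominators: gaps plus the
# alphabet's ambiguity code (X for protein, N for nucleotide)
missing_chars <- function(aln) {
  if (all(aln %in% c(NUC4, "N", "-"))) c("-", "N") else c("-", "X")
}

kmer_set <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Progressive multiple sequence alignment
#'
#' Single-pass progressive alignment: a guide tree is built by neighbor
#' joining on 3-mer distances (d = 1 - |shared 3-mers| / min set size),
#' rooted deterministically, and profiles are merged leaf-to-root with
#' profile-profile affine-gap dynamic programming. Row order equals input
#' order; the result is deterministic.
#'
#' @param records record `data.frame` (>= 2 rows, one alphabet).
#' @inheritParams align_pair_global
#' @return alignment character matrix; every row degaps to its input
#'   sequence.
#' @export
align_progressive <- function(records, matrix = "BLOSUM62",
                              gap_open = -10, gap_extend = -1) {
  if (NROW(records) < 2L) stop("need >= 2 records")
  if (length(unique(records$alphabet)) != 1L) stop("mixed alphabets")
  S <- resolve_matrix(matrix)
  ab <- rownames(S)
  ids <- records$id
  if (nrow(records) == 2L) {
    return(align_pair_global(records[1, ], records[2, ], matrix,
                             gap_open, gap_extend)$aln)
  }
  ksets <- lapply(records$seq, kmer_set)
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(ksets[[i]], ksets[[j]]))
    denom <- max(1L, min(length(ksets[[i]]), length(ksets[[j]])))
    d[i, j] <- d[j, i] <- 1 - shared / denom
  }
  guide <- neighbor_joining(as_distance_matrix(d))
  guide <- ape::root(guide, outgroup = sort(ids)[1L], resolve.root = TRUE)
  # merge sub-alignments following the guide tree, leaves to root
  merge2 <- function(A, B) {
    pa <- profile_of(A, ab); pb <- profile_of(B, ab)
    colScore <- t(pa) %*% S %*% pb
    dp <- .gotoh_dp(colScore, gap_open, gap_extend)
    la <- ncol(A); lb <- ncol(B)
    outA <- matrix("-", nrow(A), length(dp$moves), dimnames = list(rownames(A), NULL))
    outB <- matrix("-", nrow(B), length(dp$moves), dimnames = list(rownames(B), NULL))
    i <- 0L; j <- 0L
    for (k in seq_along(dp$moves)) {
      mv <- dp$moves[[k]]
      if (mv != 2L) { i <- i + 1L; outA[, k] <- A[, i] }
      if (mv != 1L) { j <- j + 1L; outB[, k] <- B[, j] }
    }
    rbind(outA, outB)
  }
  build <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    parts <- lapply(kids, function(k) {
      if (k <= length(guide$tip.label)) {
        rec <- records[records$id == guide$tip.label[[k]], , drop = FALSE]
        aln_matrix(setNames(rec$seq, rec$id))
      } else build(k)
    })
    Reduce(merge2, parts)
  }
  root_node <- setdiff(guide$edge[, 1], guide$edge[, 2])[[1]]
  aln <- build(root_node)
  aln[match(ids, rownames(aln)), , drop = FALSE]
}

#' Identity and similarity between two alignment rows
#'
#' Columns where either row carries a gap or X are excluded from the
#' denominator (pairwise deletion). Identity counts exact matches;
#' similarity counts residue pairs with a positive substitution-matrix
#' score (identities included).
#'
#' @param aln alignment matrix.
#' @param i,j row indices or row names.
#' @inheritParams align_pair_global
#' @return list with `identity_percent`, `similarity_percent`,
#'   `columns_compared`.
#' @export
pairwise_stats <- function(aln, i, j, matrix = "BLOSUM62") {
  S <- resolve_matrix(matrix)
  a <- aln[i, ]; b <- aln[j, ]
  if (length(a) != length(b)) stop("rows of unequal length")
  miss <- missing_chars(aln)
  keep <- !(a %in% miss) & !(b %in% miss)
  nc <- sum(keep)
  if (nc == 0L) stop("no comparable columns between rows ", i, " and ", j)
  a <- a[keep]; b <- b[keep]
  ident <- sum(a == b)
  simil <- sum(S[cbind(a, b)] > 0)
  list(identity_percent = 100 * ident / nc,
       similarity_percent = 100 * simil / nc,
       columns_compared = nc)
}

#' All-pairs identity/similarity matrices
#'
#' @param aln alignment matrix.
#' @inheritParams align_pair_global
#' @return list of three ids-x-ids matrices: `identity`, `similarity`,
#'   `columns` (diagonals 100/100/row length).
#' @export
pairwise_stats_matrix <- function(aln, matrix = "BLOSUM62") {
  ids <- rownames(aln)
  n <- length(ids)
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  sim <- idm
  cols <- matrix(ncol(aln), n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    st <- pairwise_stats(aln, i, j, matrix)
    idm[i, j] <- idm[j, i] <- st$identity_percent
    sim[i, j] <- sim[j, i] <- st$similarity_percent
    cols[i, j] <- cols[j, i] <- st$columns_compared
  }
  list(identity = idm, similarity = sim, columns = cols)
}

#' Majority consensus of an alignment
#'
#' Columns that are gaps in more than half of the rows are dropped. In each
#' remaining column the most frequent non-gap residue is emitted when its
#' frequency among non-gap residues reaches `threshold`; otherwise (or on a
#' tie) the ambiguity character X.
#'
#' @param aln alignment matrix (>= 2 rows).
#' @param threshold fraction in (0, 1], default 0.7.
#' @return list with `sequence` and `threshold`.
#' @export
consensus_sequence <- function(aln, threshold = 0.7) {
  if (is.null(dim(aln)) || nrow(aln) < 2L) stop("need an alignment with >= 2 rows")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  keep <- colMeans(aln == "-") <= 0.5
  cols <- which(keep)
  out <- vapply(cols, function(k) {
    res <- aln[, k]
    res <- res[res != "-"]
    tab <- sort(table(res), decreasing = TRUE)
    if (length(tab) > 1L && tab[[1]] == tab[[2]]) return("X")
    if (tab[[1]] / length(res) >= threshold) names(tab)[[1]] else "X"
  }, character(1))
  list(sequence = paste(out, collapse = ""), threshold = threshold)
}

#' Local-alignment search of a query against a target set
#'
#' Smith-Waterman optimal local alignment of the query against every
#' target, ranked by descending score with ties broken by target id.
#'
#' @param query one-row protein record or sequence string.
#' @param targets protein record `data.frame`.
#' @inheritParams align_pair_global
#' @return `data.frame` with columns `target`, `score`, `q_start`, `q_end`,
#'   `t_start`, `t_end` (1-based closed intervals; zeros when score 0).
#' @export
search_local <- function(query, targets, matrix = "BLOSUM62",
                         gap_open = -10, gap_extend = -1) {
  if (NROW(targets) == 0L) stop("empty target set")
  q <- as_named_seq(query, "query")
  S <- resolve_matrix(matrix)
  cq <- strsplit(q$seq, "")[[1]]
  res <- lapply(seq_len(nrow(targets)), function(i) {
    ct <- strsplit(targets$seq[[i]], "")[[1]]
    dp <- .sw_dp(S[cq, ct, drop = FALSE], gap_open, gap_extend)
    data.frame(target = targets$id[[i]], score = dp$score,
               q_start = dp$a_start, q_end = dp$a_end,
               t_start = dp$b_start, t_end = dp$b_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$score, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
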