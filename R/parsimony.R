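# Fitch small parsimony and heuristic tree search
# (random-addition replicas + NNI hill climbing).

# site-pattern compression: returns integer state codes per taxon
# (bitmask columns) and pattern weights. Gaps/X/N are missing data and get
# the all-states mask (neutral under Fitch union/intersection).
fitch_encode <- function(aln) {
  alphabet <- if (any(aln %in% c("C", "G")) &&
                  all(aln %in% c(NUC4, "N", "-", "X"))) NUC4 else AA20
  nstates <- length(alphabet)
  full <- bitwShiftL(1L, nstates) - 1L
  codes <- matrix(0L, nrow(aln), ncol(aln), dimnames = dimnames(aln))
  for (s in seq_len(nstates)) {
    codes[aln == alphabet[[s]]] <- bitwShiftL(1L, s - 1L)
  }
  codes[codes == 0L] <- full
  pat_key <- apply(codes, 2L, paste, collapse = ",")
  first <- !duplicated(pat_key)
  w <- as.integer(table(factor(pat_key, levels = pat_key[first])))
  list(codes = codes[, first, drop = FALSE], weights = w)
}

fitch_score_encoded <- function(tree, enc) {
  codes <- enc$codes; w <- enc$weights
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  tipidx <- match(tree$tip.label, rownames(codes))
  if (anyNA(tipidx)) stop("tree leaves and alignment ids differ")
  state <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) state[[t]] <- codes[tipidx[[t]], ]
  score <- 0L
  # fold children sequentially with the binary Fitch rule; for the
  # trifurcating root of an unrooted binary tree this equals rooting along
  # an edge, so the score is exact
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]; child <- post$edge[k, 2]
    if (is.null(state[[par]])) {
      state[[par]] <- state[[child]]
    } else {
      inter <- bitwAnd(state[[par]], state[[child]])
      z <- inter == 0L
      if (any(z)) {
        inter[z] <- bitwOr(state[[par]], state[[child]])[z]
        score <- score + sum(w[z])
      }
      state[[par]] <- inter
    }
  }
  score
}

#' Fitch parsimony score
#'
#' Minimum number of state changes over the tree, summed across alignment
#' columns (Fitch's set method). Gaps and ambiguity codes (X/N) are treated
#' as missing data.
#'
#' @param tree ape `phylo` whose leaves match the alignment rownames.
#' @param aln alignment character matrix.
#' @return integer score.
#' @export
fitch_score <- function(tree, aln) {
  if (!setequal(tree$tip.label, rownames(aln))) {
    stop("tree leaves and alignment ids differ")
  }
  fitch_score_encoded(tree, fitch_encode(aln))
}

greedy_addition_tree <- function(ids, enc, order_ids) {
  tree <- ape::read.tree(text = paste0("(", order_ids[[1]], ",",
                                       order_ids[[2]], ",",
                                       order_ids[[3]], ");"))
  tree$edge.length <- rep(1, nrow(tree$edge))
  for (id in order_ids[-(1:3)]) {
    best <- NULL
    for (k in seq_len(nrow(tree$edge))) {
      cand <- bind_tip(tree, id, k, 1)
      sc <- fitch_score_encoded(cand, enc)
      if (is.null(best) || sc < best$sc) best <- list(sc = sc, tree = cand)
    }
    tree <- best$tree
  }
  tree
}

nni_hill_climb <- function(tree, enc, score_fn = NULL) {
  score <- fitch_score_encoded(tree, enc)
  repeat {
    improved <- FALSE
    for (cand in nni_neighbors(tree)) {
      sc <- fitch_score_encoded(cand, enc)
      if (sc < score) {
        score <- sc; tree <- cand; improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(tree = tree, score = score)
}

#' Heuristic maximum-parsimony search
#'
#' Each replica builds a starting tree by greedy stepwise addition in a
#' random taxon order, then hill-climbs with nearest-neighbor interchanges
#' to a local optimum; the best-scoring tree over all replicas is returned.
#' Deterministic for a given seed.
#'
#' @param aln alignment matrix (>= 4 taxa).
#' @param n_replicas number of random-addition replicas (>= 1).
#' @param seed integer RNG seed.
#' @param nni run the NNI refinement (disable for fast bootstrap replicas).
#' @return list with `tree` (ape `phylo`), `score` (integer) and
#'   `n_replicas`.
#' @export
parsimony_search <- function(aln, n_replicas = 10L, seed = 1L, nni = TRUE) {
  if (n_replicas < 1L) stop("n_replicas must be >= 1")
  if (nrow(aln) < 4L) stop("need >= 4 taxa")
  enc <- fitch_encode(aln)
  ids <- rownames(aln)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_replicas)) {
      ord <- ids[sample.int(length(ids))]
      tree <- greedy_addition_tree(ids, enc, ord)
      res <- if (nni) nni_hill_climb(tree, enc)
             else list(tree = tree, score = fitch_score_encoded(tree, enc))
      if (is.null(best) || res$score < best$score) best <- res
    }
  })
  list(tree = best$tree, score = best$score, n_replicas = as.integer(n_replicas))
}

# evaluate expr with a local, restorable RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Parsimony replica consensus support
#'
#' Runs `n_replicas` independent random-addition + NNI searches on the
#' *original* alignment and reports, for every bipartition, the percentage
#' of replica trees containing it (the randomized-replica consensus support
#' convention of protein-parsimony programs). The returned tree is the
#' best-scoring replica annotated with those supports.
#'
#' @inheritParams parsimony_search
#' @return list with `tree`, `report` (`split`, `support`), `score`,
#'   `n_replicas`.
#' @export
parsimony_replicas <- function(aln, n_replicas = 100L, seed = 1L) {
  if (n_replicas < 2L) stop("n_replicas must be >= 2")
  if (nrow(aln) < 4L) stop("need >= 4 taxa")
  enc <- fitch_encode(aln)
  ids <- rownames(aln)
  counts <- new.env(parent = emptyenv())
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_replicas)) {
      ord <- ids[sample.int(length(ids))]
      tree <- greedy_addition_tree(ids, enc, ord)
      res <- nni_hill_climb(tree, enc)
      if (is.null(best) || res$score < best$score) best <- res
      for (key in unique(as.character(tree_splits(res$tree)))) {
        assign(key, (get0(key, envir = counts, ifnotfound = 0) + 1),
               envir = counts)
      }
    }
  })
  keys <- ls(counts)
  support <- setNames(
    vapply(keys, function(k) 100 * counts[[k]] / n_replicas, numeric(1)),
    keys)
  report <- data.frame(split = keys, support = unname(support),
                       stringsAsFactors = FALSE)
  report <- report[order(-report$support, report$split), , drop = FALSE]
  rownames(report) <- NULL
  tree <- annotate_supports(best$tree, support)
  list(tree = tree, report = report, score = best$score,
       n_replicas = as.integer(n_replicas))
}

#' Exhaustive search over all unrooted topologies
#'
#' Enumeration oracle for small taxon sets (<= 7 leaves: 945 topologies).
#' Returns the minimum Fitch score and one optimal tree.
#'
#' @param aln alignment matrix (4-7 taxa).
#' @return list with `tree`, `score`, `n_topologies`.
#' @export
parsimony_exhaustive <- function(aln) {
  ids <- rownames(aln)
  if (length(ids) > 7L) stop("exhaustive search limited to 7 taxa")
  enc <- fitch_encode(aln)
  best <- NULL
  n <- 0L
  for (tree in enumerate_topologies(ids)) {
    n <- n + 1L
    sc <- fitch_score_encoded(tree, enc)
    if (is.null(best) || sc < best$score) best <- list(tree = tree, score = sc)
  }
  list(tree = best$tree, score = best$score, n_topologies = n)
}

#' Enumerate all unrooted binary topologies on a leaf set
#'
#' Recursive edge-insertion enumeration; (2n-5)!! trees for n leaves.
#'
#' @param ids leaf ids (>= 3).
#' @param brlen branch length for every edge.
#' @return list of ape `phylo` trees.
#' @export
enumerate_topologies <- function(ids, brlen = 0.1) {
  base <- ape::read.tree(text = paste0("(", ids[[1]], ",", ids[[2]], ",",
                                       ids[[3]], ");"))
  base$edge.length <- rep(brlen, nrow(base$edge))
  trees <- list(base)
  for (id in ids[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edge)), function(k) bind_tip(tr, id, k, brlen))
    }), recursive = FALSE)
  }
  trees
}
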