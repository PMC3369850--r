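# Distance matrices, neighbor joining, bipartition utilities,
# Robinson-Foulds distance, majority-rule consensus, and NNI moves.
#
# Trees are ape `phylo` objects, treated as unrooted; internal-node labels
# carry support values in [0, 100].

#' Distance-matrix container
#'
#' Validates and wraps a symmetric nonnegative matrix (zero diagonal,
#' substitutions/site) for [neighbor_joining()].
#'
#' @param d symmetric numeric matrix with id dimnames.
#' @return the matrix, validated, with class `dist_matrix`.
#' @export
as_distance_matrix <- function(d) {
  if (is.null(rownames(d))) stop("distance matrix needs id dimnames")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stop("non-symmetric matrix")
  if (any(!is.finite(d))) stop("non-finite distances")
  if (any(diag(d) != 0)) stop("nonzero diagonal")
  if (any(d < 0)) stop("negative distances")
  class(d) <- c("dist_matrix", class(d))
  d
}

POISSON_CAP <- -log(1 / 20)

#' Pairwise distances from an alignment
#'
#' Pairwise-deletion handling: columns with a gap or ambiguity (X/N) in
#' either row are excluded for that pair. Corrections: `"p"` (raw mismatch
#' proportion), `"poisson"` (-ln(1 - p); p >= 1 - 1/20 is capped at
#' -ln(1/20) ~= 3.0 with a warning), or `"ml"` (maximum-likelihood distance
#' under the model's rate matrix, optimized numerically per pair).
#'
#' @param aln alignment matrix (>= 3 rows).
#' @param correction `"p"`, `"poisson"` or `"ml"`.
#' @param model a [subst_model()] (required for `"ml"`).
#' @return a `dist_matrix`.
#' @export
distance_matrix <- function(aln, correction = c("poisson", "p", "ml"),
                            model = NULL) {
  correction <- match.arg(correction)
  if (nrow(aln) < 3L) stop("need >= 3 rows")
  ids <- rownames(aln)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  capped <- FALSE
  miss <- missing_chars(aln)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- aln[i, ]; b <- aln[j, ]
    keep <- !(a %in% miss) & !(b %in% miss)
    if (!any(keep)) {
      stop("no comparable columns between ", ids[[i]], " and ", ids[[j]])
    }
    p <- sum(a[keep] != b[keep]) / sum(keep)
    dij <- switch(correction,
      p = p,
      poisson = if (p >= 1 - 1 / 20) { capped <- TRUE; POISSON_CAP }
                else -log(1 - p),
      ml = ml_pair_distance(a[keep], b[keep], model)
    )
    d[i, j] <- d[j, i] <- dij
  }
  if (capped) {
    warning("saturated pair(s): Poisson distance capped at ",
            signif(POISSON_CAP, 4))
  }
  as_distance_matrix(d)
}

ml_pair_distance <- function(a, b, model) {
  if (is.null(model)) stop("correction = 'ml' needs a subst_model")
  ia <- match(a, model$states); ib <- match(b, model$states)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  negll <- function(t) {
    P <- transition_prob(model, t)
    -sum(log(model$freq[ia] * P[cbind(ia, ib)]))
  }
  optimize(negll, c(1e-8, 2 * POISSON_CAP), tol = 1e-8)$minimum
}

#' Neighbor joining
#'
#' Saitou-Nei agglomeration on the Q criterion. Ties in Q are broken by the
#' lexicographically smallest id pair; negative branch lengths are clamped
#' to zero and the clamped deficit reported via a message. Exactly inverts
#' additive (four-point) matrices.
#'
#' @param dm a `dist_matrix` (>= 3 taxa).
#' @return an unrooted ape `phylo` with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  dm <- as_distance_matrix(unclass(dm))
  ids <- rownames(dm)
  n <- length(ids)
  if (n < 3L) stop("need >= 3 taxa")
  ntip <- n
  # node numbering: tips 1..ntip, internals ntip+1, ...
  node_of <- seq_len(n)             # phylo node number per cluster
  D <- unclass(dm)
  edges <- matrix(integer(), 0, 2)
  elen <- numeric()
  next_node <- ntip + 2L            # ntip+1 reserved for the final root join
  labels_of <- ids                  # cluster labels for tie-breaking
  deficit <- 0
  while (nrow(D) > 3L) {
    m <- nrow(D)
    tot <- rowSums(D)
    best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * D[i, j] - tot[[i]] - tot[[j]]
      key <- sort(c(labels_of[[i]], labels_of[[j]]))
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(q = q, i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    li <- 0.5 * D[i, j] + (tot[[i]] - tot[[j]]) / (2 * (m - 2))
    lj <- D[i, j] - li
    deficit <- deficit + min(0, li) + min(0, lj)
    li <- max(0, li); lj <- max(0, lj)
    new_node <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new_node, node_of[[i]]), c(new_node, node_of[[j]]))
    elen <- c(elen, li, lj)
    dnew <- 0.5 * (D[i, -c(i, j), drop = TRUE] + D[j, -c(i, j), drop = TRUE] -
                   D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    node_of <- c(node_of[keep], new_node)
    labels_of <- c(labels_of[keep], min(best$key))
    rownames(D) <- colnames(D) <- labels_of
  }
  # final three clusters join at the (trifurcating) root
  root <- ntip + 1L
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  deficit <- deficit + sum(pmin(0, c(l1, l2, l3)))
  edges <- rbind(edges, c(root, node_of[[1]]), c(root, node_of[[2]]),
                 c(root, node_of[[3]]))
  elen <- c(elen, max(0, l1), max(0, l2), max(0, l3))
  if (deficit < 0) {
    message("neighbor_joining: clamped negative branch length(s), total deficit ",
            signif(deficit, 3))
  }
  tree <- structure(list(edge = edges, edge.length = elen,
                         tip.label = ids, Nnode = next_node - ntip - 1L),
                    class = "phylo", order = NULL)
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

## ---- bipartitions ----------------------------------------------------

canonical_split <- function(members, all_ids) {
  anchor <- min(all_ids)
  if (anchor %in% members) members <- setdiff(all_ids, members)
  paste(sort(members), collapse = "|")
}

#' Internal bipartitions of an unrooted tree
#'
#' Each internal edge induces a split of the leaf set; splits are encoded
#' canonically as the sorted, `|`-joined side not containing the
#' alphabetically first leaf. Trivial splits (single leaf or its
#' complement) are excluded.
#'
#' @param tree an ape `phylo`.
#' @return character vector of canonical split keys; attribute `support`
#'   holds numeric node-label supports where present (NA otherwise).
#' @export
tree_splits <- function(tree) {
  ids <- tree$tip.label
  ntip <- length(ids)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) below[[t]] <- ids[[t]]
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]; child <- post$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  root <- setdiff(post$edge[, 1], post$edge[, 2])[[1]]
  keys <- character(); sup <- numeric()
  for (k in seq_len(nrow(post$edge))) {
    child <- post$edge[k, 2]
    if (child <= ntip || child == root) next
    members <- below[[child]]
    if (length(members) <= 1L || length(members) >= ntip - 1L) next
    keys <- c(keys, canonical_split(members, ids))
    s <- NA_real_
    if (!is.null(tree$node.label)) {
      lab <- tree$node.label[[child - ntip]]
      if (!is.null(lab) && nzchar(lab)) s <- suppressWarnings(as.numeric(lab))
    }
    sup <- c(sup, s)
  }
  structure(keys, support = sup)
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of internal bipartitions between two unrooted
#' trees on the same leaf set.
#'
#' @param a,b ape `phylo` trees.
#' @return integer distance.
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) stop("leaf sets differ")
  sa <- unique(as.character(tree_splits(a)))
  sb <- unique(as.character(tree_splits(b)))
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Majority-rule consensus tree
#'
#' Includes every bipartition occurring in strictly more than `rule` of the
#' input trees (strict majority: a split in exactly half of the trees at
#' `rule = 0.5` is excluded). Node labels carry occurrence percentages;
#' branch lengths are absent.
#'
#' @param trees list of ape `phylo` trees sharing one leaf set.
#' @param rule majority fraction in \[0.5, 1\].
#' @return a `phylo` consensus tree with support node labels.
#' @export
consensus_tree <- function(trees, rule = 0.5) {
  if (!length(trees)) stop("no trees")
  ids <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!setequal(t$tip.label, ids)) stop("leaf sets differ across trees")
  }
  if (rule < 0.5 || rule > 1) stop("rule must be in [0.5, 1]")
  counts <- table(unlist(lapply(trees, function(t) {
    unique(as.character(tree_splits(t)))
  })))
  freq <- as.numeric(counts) / length(trees)
  keep <- freq > rule
  build_tree_from_splits(names(counts)[keep], round(100 * freq[keep], 4), ids)
}

# Build an (unrooted, possibly multifurcating) phylo from compatible splits.
# Split keys are the side not containing the alphabetically first leaf, so
# they form a laminar family and nest into a rooted tree anchored there.
build_tree_from_splits <- function(keys, supports, ids) {
  sets <- strsplit(keys, "|", fixed = TRUE)
  ord <- order(-lengths(sets))
  sets <- sets[ord]; supports <- supports[ord]
  nest <- function(universe, idx_pool) {
    # children = maximal sets within universe
    inside <- idx_pool[vapply(idx_pool, function(i) {
      all(sets[[i]] %in% universe) && length(sets[[i]]) < length(universe)
    }, logical(1))]
    maximal <- inside[vapply(inside, function(i) {
      !any(vapply(inside, function(j) {
        j != i && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[j]]) > length(sets[[i]])
      }, logical(1)))
    }, logical(1))]
    used <- character()
    parts <- character()
    for (i in maximal) {
      sub <- nest(sets[[i]], setdiff(inside, i))
      parts <- c(parts, paste0(sub, format(supports[[i]], trim = TRUE)))
      used <- c(used, sets[[i]])
    }
    singles <- setdiff(universe, used)
    parts <- c(parts, sort(singles))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  newick <- paste0(nest(ids, seq_along(sets)), ";")
  tree <- ape::read.tree(text = newick)
  tree
}

## ---- NNI -------------------------------------------------------------

# All nearest-neighbor-interchange neighbors of an unrooted binary tree
# (2 per internal edge). Operates on ape's rooted representation: for each
# internal edge (u, v) with v internal, one u-side child subtree g is
# swapped with each child subtree of v.
nni_neighbors <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[[1]]
  out <- list()
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
    if (v <= ntip) next
    g_candidates <- tree$edge[tree$edge[, 1] == u & tree$edge[, 2] != v, 2]
    if (!length(g_candidates)) next
    g_edge <- which(tree$edge[, 1] == u & tree$edge[, 2] == g_candidates[[1]])
    v_children_edges <- which(tree$edge[, 1] == v)
    for (ce in v_children_edges) {
      t2 <- tree
      gc <- t2$edge[g_edge, 2]
      cc <- t2$edge[ce, 2]
      t2$edge[g_edge, 2] <- cc
      t2$edge[ce, 2] <- gc
      t2 <- ape::reorder.phylo(t2, "cladewise")
      out[[length(out) + 1L]] <- t2
    }
  }
  out
}

# one uniformly chosen NNI neighbor (for MCMC proposals); the proposal is
# symmetric since every unrooted binary tree has 2(n-3) NNI neighbors
nni_random <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  k <- internal[[sample.int(length(internal), 1L)]]
  u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
  g_candidates <- tree$edge[tree$edge[, 1] == u & tree$edge[, 2] != v, 2]
  g_edge <- which(tree$edge[, 1] == u & tree$edge[, 2] == g_candidates[[1]])
  v_children_edges <- which(tree$edge[, 1] == v)
  ce <- v_children_edges[[sample.int(length(v_children_edges), 1L)]]
  gc <- tree$edge[g_edge, 2]; cc <- tree$edge[ce, 2]
  tree$edge[g_edge, 2] <- cc
  tree$edge[ce, 2] <- gc
  ape::reorder.phylo(tree, "cladewise")
}

#' Generate a random unrooted binary topology
#'
#' Sequential random addition of taxa to a 3-taxon star; uses the current
#' RNG stream.
#'
#' @param ids leaf ids (>= 3).
#' @param brlen branch length assigned to every edge.
#' @return an ape `phylo`.
#' @export
random_topology <- function(ids, brlen = 0.1) {
  stopifnot(length(ids) >= 3L)
  ids <- ids[sample.int(length(ids))]
  tree <- ape::read.tree(text = paste0("(", ids[[1]], ",", ids[[2]], ",",
                                       ids[[3]], ");"))
  tree$edge.length <- rep(brlen, nrow(tree$edge))
  for (id in ids[-(1:3)]) {
    edge_k <- sample.int(nrow(tree$edge), 1L)
    tree <- bind_tip(tree, id, edge_k, brlen)
  }
  tree
}

# attach a new tip in the middle of edge k
bind_tip <- function(tree, label, k, brlen = 0.1, stem = NULL) {
  ntip <- length(tree$tip.label)
  tip_tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                             tip.label = label, edge.length = stem %||% brlen,
                             Nnode = 1L), class = "phylo")
  len <- tree$edge.length[[k]]
  ape::bind.tree(tree, tip_tree, where = tree$edge[k, 2], position = len / 2)
}
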