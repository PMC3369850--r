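# Nonparametric bootstrap over alignment columns for NJ, parsimony and ML
# trees, with per-bipartition support on the point-estimate tree.

build_tree_by_method <- function(aln, method, params, seed) {
  switch(method,
    nj = neighbor_joining(distance_matrix(aln, params$correction %||% "poisson")),
    parsimony = parsimony_search(aln,
                                 n_replicas = params$n_replicas %||% 5L,
                                 seed = seed,
                                 nni = params$nni %||% TRUE)$tree,
    ml = ml_search(aln, params$model %||% subst_model(),
                   n_starts = params$n_starts %||% 1L, seed = seed)$tree,
    stop("unknown method: ", method)
  )
}

#' Bootstrap support for a tree-building method
#'
#' Resamples alignment columns with replacement, reruns the method on each
#' replicate, and reports for every internal bipartition of the
#' point-estimate tree the percentage of replicate trees containing it.
#' Supports below 50 are retained in the data (display layers may mask
#' them). Deterministic given the seed.
#'
#' @param aln alignment matrix (>= 4 taxa).
#' @param method `"nj"`, `"parsimony"` or `"ml"`.
#' @param n_replicates number of bootstrap replicates (>= 2; default 100).
#' @param seed RNG seed.
#' @param params method parameters: `correction` (nj); `n_replicas`, `nni`
#'   (parsimony); `model`, `n_starts` (ml).
#' @return list with `tree` (point estimate, node labels = supports),
#'   `report` (data.frame: `split`, `support`), `n_replicates`.
#' @export
bootstrap <- function(aln, method = c("nj", "parsimony", "ml"),
                      n_replicates = 100L, seed = 1L, params = list()) {
  method <- match.arg(method)
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (nrow(aln) < 4L) stop("need >= 4 taxa")
  point <- build_tree_by_method(aln, method, params, seed)
  point_splits <- unique(as.character(tree_splits(point)))
  hit <- setNames(numeric(length(point_splits)), point_splits)
  all_counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      rep_aln <- aln[, cols, drop = FALSE]
      rep_seed <- sample.int(.Machine$integer.max, 1L)
      rep_tree <- tryCatch(build_tree_by_method(rep_aln, method, params, rep_seed),
                           error = function(e) NULL)
      if (is.null(rep_tree)) next
      rs <- unique(as.character(tree_splits(rep_tree)))
      shared <- intersect(rs, point_splits)
      hit[shared] <- hit[shared] + 1
      for (key in rs) all_counts[[key]] <- (all_counts[[key]] %||% 0) + 1
    }
  })
  support <- 100 * hit / n_replicates
  tree <- annotate_supports(point, support)
  report <- data.frame(split = names(support), support = unname(support),
                       stringsAsFactors = FALSE)
  report <- report[order(-report$support, report$split), , drop = FALSE]
  rownames(report) <- NULL
  list(tree = tree, report = report, n_replicates = as.integer(n_replicates),
       method = method)
}

# write split supports into a tree's internal node labels
annotate_supports <- function(tree, support) {
  ids <- tree$tip.label
  ntip <- length(ids)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) below[[t]] <- ids[[t]]
  for (k in seq_len(nrow(post$edge))) {
    below[[post$edge[k, 1]]] <- c(below[[post$edge[k, 1]]],
                                  below[[post$edge[k, 2]]])
  }
  root <- setdiff(post$edge[, 1], post$edge[, 2])[[1]]
  labels <- rep("", tree$Nnode)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    if (node == root) next
    members <- below[[node]]
    if (length(members) <= 1L || length(members) >= ntip - 1L) next
    key <- canonical_split(members, ids)
    if (key %in% names(support)) {
      labels[[node - ntip]] <- format(round(support[[key]], 1), trim = TRUE)
    }
  }
  tree$node.label <- labels
  tree
}

#' Write a bipartition-support report TSV
#'
#' @param report `data.frame` with `split` and `support` columns (from
#'   [bootstrap()] or [mcmc_sample()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_support_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
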