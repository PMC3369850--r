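# The molecular-piracy test: turn trees plus a viral/host label map into a
# quantitative verdict.
#
# The hypothesis contrast: if viral channels were recently pirated from
# their hosts, each viral gene should branch inside its own host species'
# channel family ("host-nested"); if the viral lineage diverged before host
# speciation, the viral channels form their own clade separate from all
# host paralogs ("independent-clade"). On unrooted trees a viral clade
# exists in both scenarios, so the verdict also inspects where the clade
# attaches: the smallest bipartition side containing a viral taxon plus at
# least one non-viral taxon.

#' Monophyly on an unrooted tree
#'
#' A taxon set is monophyletic iff some bipartition of the tree separates
#' exactly that set from the rest (trivial splits of one leaf, or all but
#' one, always qualify).
#'
#' @param tree ape `phylo`.
#' @param taxa character vector of leaf ids.
#' @return logical.
#' @export
is_monophyletic <- function(tree, taxa) {
  ids <- tree$tip.label
  unknown <- setdiff(taxa, ids)
  if (length(unknown)) stop("unknown id: ", unknown[[1]])
  n <- length(ids)
  k <- length(unique(taxa))
  if (k <= 1L || k >= n - 1L) return(TRUE)
  key <- canonical_split(unique(taxa), ids)
  key %in% as.character(tree_splits(tree))
}

#' Support for an exact bipartition
#'
#' Looks up the bootstrap or posterior support of the bipartition
#' `{taxa | rest}` in a support report; 0 when the bipartition is absent,
#' 100 for trivial splits.
#'
#' @param report `data.frame` with `split`, `support` (from [bootstrap()]
#'   or [mcmc_sample()]), or the list those functions return.
#' @param taxa leaf id set.
#' @param all_ids the full leaf set the report refers to.
#' @return support in \[0, 100\].
#' @export
clade_support <- function(report, taxa, all_ids) {
  if (is.list(report) && !is.data.frame(report)) {
    report <- report$report %||% report$splits
  }
  k <- length(unique(taxa))
  if (k <= 1L || k >= length(all_ids) - 1L) return(100)
  key <- canonical_split(unique(taxa), all_ids)
  hit <- match(key, report$split)
  if (is.na(hit)) 0 else report$support[[hit]]
}

#' Flag proviral copies in the host set
#'
#' A host-labeled record nearly identical to a viral record is most likely
#' an integrated (lysogenic) copy of the viral gene itself and would fake a
#' host-nested signal; any host record with identity at or above
#' `threshold` percent to any viral record is excluded from the host set
#' before the piracy test.
#'
#' @param labels label-map `data.frame` (columns `id`, `role`).
#' @param identity ids-x-ids identity matrix (percent), e.g. from
#'   [pairwise_stats_matrix()].
#' @param threshold identity percent (default 95).
#' @return character vector of excluded host ids (possibly empty).
#' @export
proviral_exclusion <- function(labels, identity, threshold = 95) {
  viral <- labels$id[labels$role == "viral"]
  hosts <- labels$id[labels$role == "host"]
  viral <- intersect(viral, rownames(identity))
  hosts <- intersect(hosts, rownames(identity))
  if (!length(viral) || !length(hosts)) return(character())
  excluded <- hosts[vapply(hosts, function(h) {
    any(identity[h, viral] >= threshold)
  }, logical(1))]
  if (length(excluded)) {
    message("proviral exclusion (>= ", threshold, "% identity to a viral record): ",
            paste(excluded, collapse = ", "))
  }
  excluded
}

# smallest bipartition side containing taxon `x` and at least one id not in
# `group`; returns the member ids of that side (NULL when none exists)
smallest_mixed_clade <- function(tree, x, group) {
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
  best <- NULL
  for (node in seq_len(ntip + tree$Nnode)) {
    if (node == root) next
    members <- below[[node]]
    side2 <- setdiff(ids, members)
    for (side in list(members, side2)) {
      if (x %in% side && length(setdiff(side, group)) > 0) {
        if (is.null(best) || length(side) < length(best)) best <- side
      }
    }
  }
  best
}

#' Run the molecular-piracy test
#'
#' Builds trees with support by each requested method (bootstrap for NJ and
#' ML, random-addition replica consensus for parsimony, posterior split
#' frequencies for MCMC), tests viral monophyly and clade support, inspects
#' where the viral clade attaches, and aggregates a verdict:
#' * `host-nested` - in at least one method, every viral taxon's smallest
#'   enclosing clade that contains a non-viral taxon is host-specific: all
#'   its non-viral members are host records from that viral taxon's own
#'   host species (requires a species/source mapping).
#' * `independent-clade` - not host-nested, and every method finds the
#'   viral set monophyletic with support at or above `min_support`.
#' * `ambiguous` - anything else.
#'
#' Host records nearly identical to a viral record (proviral copies, e.g. a
#' lysogenically integrated genome) are excluded first; see
#' [proviral_exclusion()].
#'
#' @param aln alignment matrix over all analyzed taxa.
#' @param labels label map `data.frame` (`id`, `role`, optional `source` =
#'   host species; for viral records `source` is the species the virus
#'   infects).
#' @param methods subset of `"nj"`, `"parsimony"`, `"ml"`, `"mcmc"`.
#' @param params list: `min_support` (default 95), `n_bootstrap` (default
#'   100), `proviral_threshold` (default 95), `mcmc_iterations`,
#'   `mcmc_burn_in`, per-method params as in [bootstrap()].
#' @param seed RNG seed.
#' @return a `piracy_verdict` list: `verdict`, `per_method`,
#'   `excluded_ids`, `methods_agreeing`, `params`.
#' @export
run_piracy_test <- function(aln, labels, methods = c("nj", "parsimony"),
                            params = list(), seed = 1L) {
  p <- modifyList(list(min_support = 95, n_bootstrap = 100L,
                       proviral_threshold = 95, mcmc_iterations = 4000L,
                       mcmc_burn_in = 1000L, model = subst_model(),
                       nj = list(),
                       parsimony = list(n_replicas = 1L, nni = TRUE),
                       ml = list()),
                  params)
  methods <- match.arg(methods, c("nj", "parsimony", "ml", "mcmc"),
                       several.ok = TRUE)
  labels <- labels[labels$id %in% rownames(aln), , drop = FALSE]
  stats <- pairwise_stats_matrix(aln)
  excluded <- proviral_exclusion(labels, stats$identity, p$proviral_threshold)
  keep_ids <- setdiff(labels$id, excluded)
  aln2 <- aln[keep_ids, , drop = FALSE]
  aln2 <- aln2[, colSums(aln2 != "-") > 0, drop = FALSE]
  lab2 <- labels[match(keep_ids, labels$id), , drop = FALSE]
  viral <- lab2$id[lab2$role == "viral"]
  host <- lab2$id[lab2$role == "host"]
  if (length(viral) < 2L || length(host) < 2L) {
    stop("need >= 2 viral and >= 2 host taxa after proviral exclusion")
  }
  if (nrow(aln2) < 4L) stop("fewer than 4 taxa total")
  species_of <- setNames(lab2$source, lab2$id)
  per_method <- list()
  for (m in methods) {
    if (m == "mcmc") {
      res <- mcmc_sample(aln2, p$model, n_iterations = p$mcmc_iterations,
                         burn_in = p$mcmc_burn_in, seed = seed)
      tree <- res$consensus
      report <- res$splits
    } else if (m == "parsimony") {
      # support = consensus over random-addition search replicas on the
      # original alignment (the protpars randomized-replica convention)
      res <- parsimony_replicas(aln2, n_replicas = p$n_bootstrap, seed = seed)
      tree <- res$tree
      report <- res$report
    } else {
      mp <- p[[m]] %||% list()
      if (m == "ml") mp$model <- mp$model %||% p$model
      res <- bootstrap(aln2, m, n_replicates = p$n_bootstrap, seed = seed,
                       params = mp)
      tree <- res$tree
      report <- res$report
    }
    mono <- is_monophyletic(tree, viral)
    supp <- clade_support(report, viral, rownames(aln2))
    nested <- method_host_nested(tree, viral, lab2, species_of)
    per_method[[m]] <- list(
      tree = tree, report = report,
      viral_monophyletic = mono,
      viral_clade_support = supp,
      nearest_host_partner = nearest_host_partner(tree, viral, host),
      host_nested = nested
    )
  }
  any_nested <- any(vapply(per_method, `[[`, logical(1), "host_nested"))
  all_mono_supported <- all(vapply(per_method, function(x) {
    x$viral_monophyletic && x$viral_clade_support >= p$min_support
  }, logical(1)))
  verdict <- if (any_nested) "host-nested"
             else if (all_mono_supported) "independent-clade"
             else "ambiguous"
  agree_fn <- switch(verdict,
    "host-nested" = function(x) x$host_nested,
    "independent-clade" = function(x) {
      x$viral_monophyletic && x$viral_clade_support >= p$min_support
    },
    function(x) !x$host_nested &&
      !(x$viral_monophyletic && x$viral_clade_support >= p$min_support)
  )
  structure(list(
    verdict = verdict,
    per_method = per_method,
    excluded_ids = excluded,
    methods_agreeing = sum(vapply(per_method, agree_fn, logical(1))),
    params = p[c("min_support", "n_bootstrap", "proviral_threshold")],
    seed = seed
  ), class = "piracy_verdict")
}

# nested iff every viral taxon's smallest mixed clade is pure host of the
# taxon's own host species
method_host_nested <- function(tree, viral, labels, species_of) {
  if (all(is.na(species_of))) return(FALSE)
  role_of <- setNames(labels$role, labels$id)
  for (v in viral) {
    clade <- smallest_mixed_clade(tree, v, viral)
    if (is.null(clade)) return(FALSE)
    nonviral <- setdiff(clade, viral)
    if (!length(nonviral)) return(FALSE)
    if (any(role_of[nonviral] != "host")) return(FALSE)
    own <- species_of[[v]]
    if (is.na(own)) return(FALSE)
    if (any(species_of[nonviral] != own)) return(FALSE)
  }
  TRUE
}

nearest_host_partner <- function(tree, viral, host) {
  sizes <- vapply(viral, function(v) {
    clade <- smallest_mixed_clade(tree, v, viral)
    hosts <- intersect(clade, host)
    if (length(hosts)) length(clade) else NA_integer_
  }, integer(1))
  if (all(is.na(sizes))) return(NA_character_)
  v <- viral[[which.min(sizes)]]
  hosts <- sort(intersect(smallest_mixed_clade(tree, v, viral), host))
  if (length(hosts)) hosts[[1]] else NA_character_
}

#' @export
print.piracy_verdict <- function(x, ...) {
  cat("Molecular-piracy test\n")
  cat("  verdict:          ", x$verdict, "\n")
  cat("  methods agreeing: ", x$methods_agreeing, "of", length(x$per_method), "\n")
  if (length(x$excluded_ids)) {
    cat("  excluded (proviral):", paste(x$excluded_ids, collapse = ", "), "\n")
  }
  for (m in names(x$per_method)) {
    pm <- x$per_method[[m]]
    cat(sprintf("  %-9s monophyletic=%s support=%.1f nearest_host=%s nested=%s\n",
                m, pm$viral_monophyletic, pm$viral_clade_support,
                pm$nearest_host_partner, pm$host_nested))
  }
  invisible(x)
}

#' Serialize a piracy verdict to JSON
#'
#' @param verdict a `piracy_verdict`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_verdict_json <- function(verdict, path) {
  out <- list(
    verdict = verdict$verdict,
    methods_agreeing = verdict$methods_agreeing,
    excluded_ids = verdict$excluded_ids,
    params = verdict$params,
    seed = verdict$seed,
    per_method = lapply(verdict$per_method, function(pm) {
      list(viral_monophyletic = pm$viral_monophyletic,
           viral_clade_support = pm$viral_clade_support,
           nearest_host_partner = pm$nearest_host_partner,
           host_nested = pm$host_nested,
           tree = write_newick(pm$tree))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
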