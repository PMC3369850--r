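# Substitution models, Felsenstein pruning likelihood, and heuristic
# maximum-likelihood tree search.

#' Substitution models
#'
#' Two model families: `"JC69-nucleotide"` (equal rates, equal base
#' frequencies) and `"empirical-protein"` (exchangeabilities and
#' equilibrium frequencies from a bundled table; default WAG). Rates are
#' normalized so the expected number of substitutions per site per unit
#' branch length is 1. Among-site rate variation uses a discrete gamma with
#' `n_rate_categories` equal-weight categories (category means).
#'
#' @param kind `"empirical-protein"` or `"JC69-nucleotide"`.
#' @param gamma_shape positive shape parameter, or `NULL` for uniform rates.
#' @param n_rate_categories number of discrete gamma categories (default 4).
#' @return a `subst_model` list: `states`, `freq`, `Q`, eigendecomposition,
#'   `gamma_shape`, `n_rate_categories`.
#' @export
subst_model <- function(kind = c("empirical-protein", "JC69-nucleotide"),
                        gamma_shape = NULL, n_rate_categories = 4L) {
  kind <- match.arg(kind)
  if (kind == "empirical-protein") {
    wag <- load_wag()
    states <- rownames(wag$S)
    freq <- wag$freq
    Q <- wag$S %*% diag(freq)
  } else {
    states <- NUC4
    freq <- setNames(rep(0.25, 4), states)
    Q <- matrix(0.25, 4, 4, dimnames = list(states, states))
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(freq * diag(Q))
  Q <- Q / mean_rate
  # reversible Q: symmetrize with sqrt(pi) for a stable eigendecomposition
  sp <- sqrt(freq)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (!is.null(gamma_shape) && gamma_shape <= 0) stop("gamma_shape must be > 0")
  structure(list(kind = kind, states = states, freq = freq, Q = Q,
                 evec = diag(1 / sp) %*% eig$vectors,
                 ivec = t(eig$vectors) %*% diag(sp),
                 eval = eig$values,
                 gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories)),
            class = "subst_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [subst_model()].
#' @param t branch length in expected substitutions/site (>= 0).
#' @return stochastic matrix over the model's states.
#' @export
transition_prob <- function(model, t) {
  if (t < 0) stop("negative branch length")
  P <- model$evec %*% diag(exp(model$eval * t)) %*% model$ivec
  P[P < 0] <- 0
  P
}

#' Discrete-gamma rate categories (category means, equal weights)
#'
#' Mean rate of each of `k` equal-probability slices of a Gamma(shape,
#' rate = shape) distribution; the category rates average to 1.
#'
#' @param shape gamma shape parameter alpha (> 0).
#' @param k number of categories.
#' @return numeric vector of k rates.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  if (shape <= 0) stop("shape must be > 0")
  bounds <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  # mean of a Gamma(a, a) over [l, u] slice with probability 1/k:
  # k * (F_{a+1}(u) - F_{a+1}(l)) where F is the cdf with shape a + 1
  k * (pgamma(bounds[-1], shape = shape + 1, rate = shape) -
       pgamma(bounds[-(k + 1)], shape = shape + 1, rate = shape))
}

model_rates <- function(model) {
  if (is.null(model$gamma_shape)) 1
  else discrete_gamma_rates(model$gamma_shape, model$n_rate_categories)
}

# encode alignment columns as state indices (NA = missing) with site-pattern
# compression
likelihood_encode <- function(aln, model) {
  idx <- matrix(match(aln, model$states), nrow(aln), ncol(aln),
                dimnames = dimnames(aln))
  key <- apply(idx, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.integer(table(factor(key, levels = key[first])))
  list(idx = idx[, first, drop = FALSE], weights = w)
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of an alignment on a tree with branch
#' lengths under a [subst_model()]. Gaps and ambiguity codes are missing
#' data (all-ones partial likelihood); with a gamma shape set, each column's
#' likelihood is averaged over the discrete rate categories.
#'
#' @param tree ape `phylo` with `edge.length` (leaves = alignment rows).
#' @param aln alignment character matrix.
#' @param model a [subst_model()].
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(tree, aln, model) {
  if (is.null(dim(aln)) || ncol(aln) == 0L) stop("zero-length alignment")
  if (!setequal(tree$tip.label, rownames(aln))) {
    stop("tree leaves and alignment ids differ")
  }
  if (model$kind == "JC69-nucleotide" && !all(aln %in% c(NUC4, "N", "-", "X"))) {
    stop("nucleotide model applied to a protein alignment")
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  enc <- likelihood_encode(aln, model)
  ll_encoded(tree, enc, model)
}

ll_encoded <- function(tree, enc, model) {
  nst <- length(model$states)
  npat <- ncol(enc$idx)
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  tipidx <- match(tree$tip.label, rownames(enc$idx))
  rates <- model_rates(model)
  site_lik <- matrix(0, length(rates), npat)
  for (rc in seq_along(rates)) {
    r <- rates[[rc]]
    cond <- vector("list", ntip + tree$Nnode)
    for (t in seq_len(ntip)) {
      m <- matrix(0, nst, npat)
      s <- enc$idx[tipidx[[t]], ]
      obs <- !is.na(s)
      m[cbind(s[obs], which(obs))] <- 1
      m[, !obs] <- 1
      cond[[t]] <- m
    }
    for (k in seq_len(nrow(post$edge))) {
      par <- post$edge[k, 1]; child <- post$edge[k, 2]
      P <- transition_prob(model, post$edge.length[[k]] * r)
      msg <- P %*% cond[[child]]
      cond[[par]] <- if (is.null(cond[[par]])) msg else cond[[par]] * msg
    }
    root <- setdiff(post$edge[, 1], post$edge[, 2])[[1]]
    site_lik[rc, ] <- as.numeric(model$freq %*% cond[[root]])
  }
  site <- colMeans(site_lik)
  if (any(site <= 0)) return(-Inf)
  sum(enc$weights * log(site))
}

optimize_branch_lengths <- function(tree, enc, model, tol = 1e-6,
                                    max_sweeps = 3L, upper = 10) {
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (k in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        t2 <- tree; t2$edge.length[[k]] <- x
        -ll_encoded(t2, enc, model)
      }
      opt <- optimize(f, c(0, upper), tol = tol)
      if (abs(opt$minimum - tree$edge.length[[k]]) > tol) changed <- TRUE
      tree$edge.length[[k]] <- opt$minimum
    }
    if (!changed) break
  }
  tree
}

#' Heuristic maximum-likelihood tree search
#'
#' Starts from a neighbor-joining tree (Poisson or JC distances) plus
#' optional random-topology restarts; alternates per-branch scalar
#' optimization (tolerance 1e-6 substitutions/site) with
#' nearest-neighbor-interchange moves, accepting a move only when it
#' improves the log-likelihood by more than 1e-8. Deterministic given the
#' seed. When `optimize_gamma` is set, the gamma shape is refined by
#' golden-section search on [0.05, 10].
#'
#' @param aln alignment matrix (>= 4 taxa).
#' @param model a [subst_model()].
#' @param n_starts number of starting trees (1 = NJ only).
#' @param seed RNG seed for the random restarts.
#' @param optimize_gamma re-estimate `gamma_shape` during the search.
#' @return list with `tree` (optimized branch lengths), `log_likelihood`,
#'   `model`.
#' @export
ml_search <- function(aln, model = subst_model(), n_starts = 1L, seed = 1L,
                      optimize_gamma = FALSE) {
  if (nrow(aln) < 4L) stop("need >= 4 taxa")
  if (model$kind == "JC69-nucleotide" && !all(aln %in% c(NUC4, "N", "-", "X"))) {
    stop("model/alphabet mismatch")
  }
  enc <- likelihood_encode(aln, model)
  dm <- distance_matrix(aln, "poisson")
  starts <- list(neighbor_joining(dm))
  if (n_starts > 1L) {
    with_seed(seed, {
      for (s in seq_len(n_starts - 1L)) {
        starts[[length(starts) + 1L]] <- random_topology(rownames(aln), 0.1)
      }
    })
  }
  best <- NULL
  for (tree in starts) {
    tree$edge.length[tree$edge.length < 1e-6] <- 1e-6
    tree <- optimize_branch_lengths(tree, enc, model)
    ll <- ll_encoded(tree, enc, model)
    repeat {
      cand_best <- NULL
      for (cand in nni_neighbors(tree)) {
        cll <- ll_encoded(cand, enc, model)
        if (is.null(cand_best) || cll > cand_best$ll) {
          cand_best <- list(tree = cand, ll = cll)
        }
      }
      if (!is.null(cand_best)) {
        cand_tree <- optimize_branch_lengths(cand_best$tree, enc, model)
        cll <- ll_encoded(cand_tree, enc, model)
        if (cll > ll + 1e-8) {
          tree <- cand_tree; ll <- cll
          next
        }
      }
      break
    }
    if (optimize_gamma && !is.null(model$gamma_shape)) {
      gopt <- optimize(function(a) {
        m2 <- model; m2$gamma_shape <- a
        -ll_encoded(tree, enc, m2)
      }, c(0.05, 10), tol = 1e-4)
      model$gamma_shape <- gopt$minimum
      tree <- optimize_branch_lengths(tree, enc, model)
      ll <- ll_encoded(tree, enc, model)
    }
    if (is.null(best) || ll > best$log_likelihood) {
      best <- list(tree = tree, log_likelihood = ll, model = model)
    }
  }
  best
}

#' Brute-force likelihood by ancestral-state enumeration
#'
#' Independent oracle for [log_likelihood()]: sums the joint probability
#' over every combination of internal-node states, per column. Exponential
#' in the number of internal nodes; intended for <= 5 taxa and short
#' alignments.
#'
#' @inheritParams log_likelihood
#' @return log-likelihood.
#' @export
log_likelihood_bruteforce <- function(tree, aln, model) {
  enc <- list(idx = matrix(match(aln, model$states), nrow(aln), ncol(aln),
                           dimnames = dimnames(aln)))
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  nst <- length(model$states)
  post <- ape::reorder.phylo(tree, "postorder")
  root <- setdiff(post$edge[, 1], post$edge[, 2])[[1]]
  rates <- model_rates(model)
  tipidx <- match(tree$tip.label, rownames(enc$idx))
  total <- 0
  for (col in seq_len(ncol(aln))) {
    site <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(post$edge)), function(k) {
        transition_prob(model, post$edge.length[[k]] * r)
      })
      # enumerate internal-node states
      grid <- as.matrix(expand.grid(rep(list(seq_len(nst)), nint)))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign_state <- function(node) {
          if (node <= ntip) enc$idx[tipidx[[node]], col]
          else grid[g, node - ntip]
        }
        p <- model$freq[[assign_state(root)]]
        ok <- TRUE
        for (k in seq_len(nrow(post$edge))) {
          a <- assign_state(post$edge[k, 1])
          b <- assign_state(post$edge[k, 2])
          if (is.na(b)) next # missing tip: marginalize = sum over states
          if (is.na(a)) { ok <- FALSE; break }
          p <- p * Ps[[k]][a, b]
        }
        if (ok) lik <- lik + p
      }
      site <- site + lik / length(rates)
    }
    total <- total + log(site)
  }
  total
}
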