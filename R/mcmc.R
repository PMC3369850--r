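# Bayesian MCMC over tree topologies and branch lengths
# (Metropolis-Hastings; NNI topology proposals, multiplier branch-length
# proposals, exponential branch-length prior, uniform topology prior).

#' Posterior sampling of phylogenies by Metropolis-Hastings MCMC
#'
#' Each iteration proposes either a uniformly chosen nearest-neighbor
#' interchange (probability 0.5) or a multiplier update of one branch
#' length (`t' = t * exp(lambda(u - 1/2))`, Hastings ratio `t'/t`). The
#' prior is exponential (mean `prior_mean`) on branch lengths and uniform
#' over unrooted topologies. Two independent chains are run; after burn-in,
#' per-bipartition posterior frequencies are recorded every
#' `sample_every` iterations, and chain agreement is summarized by the
#' average standard deviation of split frequencies (ASDSF, computed over
#' splits reaching 10% in at least one chain).
#'
#' @param aln alignment matrix (>= 4 taxa).
#' @param model a [subst_model()].
#' @param n_iterations iterations per chain.
#' @param burn_in iterations discarded (must be < `n_iterations`).
#' @param seed integer seed (chains use seed and seed + 1).
#' @param n_chains number of independent chains (default 2).
#' @param sample_every thinning interval.
#' @param prior_mean exponential prior mean for branch lengths
#'   (substitutions/site, default 0.1).
#' @param lambda multiplier proposal tuning constant.
#' @return list with `splits` (data.frame: split key, posterior percent),
#'   `consensus` (majority-rule consensus of sampled trees), `asdsf`,
#'   `per_chain` (split frequencies per chain), `n_samples`.
#' @export
mcmc_sample <- function(aln, model = subst_model(), n_iterations = 2000L,
                        burn_in = 500L, seed = 1L, n_chains = 2L,
                        sample_every = 10L, prior_mean = 0.1, lambda = 1.5) {
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations")
  if (nrow(aln) < 4L) stop("need >= 4 taxa")
  enc <- likelihood_encode(aln, model)
  ids <- sort(rownames(aln))
  chains <- lapply(seq_len(n_chains), function(ch) {
    with_seed(seed + ch - 1L, {
      run_chain(aln, enc, model, n_iterations, burn_in, sample_every,
                prior_mean, lambda)
    })
  })
  all_keys <- unique(unlist(lapply(chains, function(c) names(c$split_freq))))
  freq_mat <- vapply(chains, function(c) {
    f <- c$split_freq[all_keys]
    f[is.na(f)] <- 0
    unname(f)
  }, numeric(length(all_keys)))
  freq_mat <- matrix(freq_mat, nrow = length(all_keys))
  rownames(freq_mat) <- all_keys
  mean_freq <- rowMeans(freq_mat)
  relevant <- apply(freq_mat, 1L, max) >= 0.10
  asdsf <- if (any(relevant) && n_chains > 1L) {
    mean(apply(freq_mat[relevant, , drop = FALSE], 1L, stats::sd))
  } else 0
  splits <- data.frame(split = all_keys, support = 100 * mean_freq,
                       stringsAsFactors = FALSE)
  splits <- splits[order(-splits$support, splits$split), , drop = FALSE]
  rownames(splits) <- NULL
  keep <- splits$support > 50
  consensus <- build_tree_from_splits(splits$split[keep],
                                      round(splits$support[keep], 4),
                                      ids)
  list(splits = splits, consensus = consensus, asdsf = asdsf,
       per_chain = freq_mat, n_samples = chains[[1]]$n_samples)
}

run_chain <- function(aln, enc, model, n_iterations, burn_in, sample_every,
                      prior_mean, lambda) {
  # desk-scale chains start from an NJ tree perturbed by a few random NNI
  # moves (chains differ through the RNG stream); purely random starting
  # topologies mix too slowly at these chain lengths
  tree <- tryCatch(
    suppressMessages(neighbor_joining(distance_matrix(aln, "poisson"))),
    error = function(e) random_topology(rownames(aln), prior_mean))
  for (k in seq_len(sample.int(3L, 1L))) tree <- nni_random(tree)
  tree$edge.length[tree$edge.length < 1e-4] <- 1e-4
  ll <- ll_encoded(tree, enc, model)
  log_prior <- function(t) sum(-t$edge.length / prior_mean)
  lp <- log_prior(tree)
  counts <- new.env(parent = emptyenv())
  n_samples <- 0L
  for (it in seq_len(n_iterations)) {
    u_move <- runif(1)
    if (u_move < 0.5) { # NNI (symmetric proposal)
      cand <- nni_random(tree)
      cll <- ll_encoded(cand, enc, model)
      clp <- log_prior(cand)
      if (log(runif(1)) < (cll + clp) - (ll + lp)) {
        tree <- cand; ll <- cll; lp <- clp
      }
    } else if (u_move < 0.9) { # branch-length multiplier
      k <- sample.int(nrow(tree$edge), 1L)
      mult <- exp(lambda * (runif(1) - 0.5))
      cand <- tree
      cand$edge.length[[k]] <- tree$edge.length[[k]] * mult
      cll <- ll_encoded(cand, enc, model)
      clp <- log_prior(cand)
      if (log(runif(1)) < (cll + clp) - (ll + lp) + log(mult)) {
        tree <- cand; ll <- cll; lp <- clp
      }
    } else { # redraw one length from the prior (acceptance = likelihood ratio)
      k <- sample.int(nrow(tree$edge), 1L)
      cand <- tree
      cand$edge.length[[k]] <- rexp(1, 1 / prior_mean)
      cll <- ll_encoded(cand, enc, model)
      if (log(runif(1)) < cll - ll) {
        tree <- cand; ll <- cll; lp <- log_prior(tree)
      }
    }
    if (it > burn_in && (it - burn_in) %% sample_every == 0L) {
      n_samples <- n_samples + 1L
      for (key in unique(as.character(tree_splits(tree)))) {
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]] / n_samples, numeric(1))
  list(split_freq = setNames(freq, keys), n_samples = n_samples)
}

#' Exact 4-taxon posterior by quadrature (oracle)
#'
#' Independent check for [mcmc_sample()]: for four taxa there are three
#' unrooted topologies; the marginal likelihood of each is integrated over
#' its five branch lengths on a grid under the same exponential prior, and
#' the posterior is the normalized product with the uniform topology prior.
#'
#' @param aln 4-row alignment matrix.
#' @param model a [subst_model()].
#' @param prior_mean exponential prior mean for branch lengths.
#' @param grid branch-length quadrature nodes (default 6 per branch).
#' @return named numeric vector: posterior probability per topology (named
#'   by the canonical split of each topology).
#' @export
posterior_quadrature_4taxa <- function(aln, model, prior_mean = 0.1,
                                       grid = 6L) {
  stopifnot(nrow(aln) == 4L)
  ids <- sort(rownames(aln))
  enc <- likelihood_encode(aln, model)
  topos <- enumerate_topologies(rownames(aln))
  stopifnot(length(topos) == 3L)
  # Gauss-Legendre-style quadrature via equal-probability slices of the
  # exponential prior: node = slice median, weight = 1/grid
  qs <- (seq_len(grid) - 0.5) / grid
  nodes <- -prior_mean * log(1 - qs)
  log_marg <- vapply(topos, function(tr) {
    ne <- nrow(tr$edge)
    combos <- as.matrix(expand.grid(rep(list(seq_len(grid)), ne)))
    lls <- vapply(seq_len(nrow(combos)), function(g) {
      tr$edge.length <- nodes[combos[g, ]]
      ll_encoded(tr, enc, model)
    }, numeric(1))
    m <- max(lls)
    m + log(mean(exp(lls - m)))
  }, numeric(1))
  post <- exp(log_marg - max(log_marg))
  post <- post / sum(post)
  names(post) <- vapply(topos, function(tr) {
    s <- as.character(tree_splits(tr))
    if (length(s)) s else ""
  }, character(1))
  post
}
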