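# Shared fixtures and independent oracles used across test files.

NUC <- c("A", "C", "G", "T")

# simulate a nucleotide alignment on a tree under a substitution model by
# direct ancestral sampling (independent of the pruning machinery)
sim_alignment <- function(tree, L, model = subst_model("JC69-nucleotide")) {
  post <- ape::reorder.phylo(tree, "cladewise")
  root <- setdiff(post$edge[, 1], post$edge[, 2])[[1]]
  st <- vector("list", ape::Ntip(tree) + tree$Nnode)
  st[[root]] <- sample(model$states, L, TRUE, prob = model$freq)
  for (k in seq_len(nrow(post$edge))) {
    P <- transition_prob(model, post$edge.length[[k]])
    dimnames(P) <- list(model$states, model$states)
    st[[post$edge[k, 2]]] <- vapply(st[[post$edge[k, 1]]], function(x) {
      sample(model$states, 1L, prob = P[x, ])
    }, character(1))
  }
  m <- do.call(rbind, st[seq_len(ape::Ntip(tree))])
  rownames(m) <- tree$tip.label
  m
}

# brute-force optimal global affine alignment score by enumerating every
# alignment (exponential; lengths <= 5)
enumerate_global_score <- function(a, b, S, go, ge) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, score + S[ca[[i]], cb[[j]]], "m")
    }
    if (i <= length(ca)) {
      rec(i + 1L, j, score + if (last == "a") ge else go, "a")
    }
    if (j <= length(cb)) {
      rec(i, j + 1L, score + if (last == "b") ge else go, "b")
    }
  }
  rec(1L, 1L, 0, "m")
  best
}

# minimum number of changes for one column by exhaustive enumeration of
# ancestral states (independent Fitch oracle)
enumerate_column_changes <- function(tree, states) {
  post <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  obs <- unique(states[!is.na(states)])
  if (length(obs) <= 1L) return(0L)
  nint <- tree$Nnode
  grid <- expand.grid(rep(list(obs), nint), stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    state_of <- function(n) {
      if (n <= ntip) states[[match(tree$tip.label[[n]], names(states))]]
      else grid[g, n - ntip]
    }
    changes <- 0L
    for (k in seq_len(nrow(post$edge))) {
      a <- state_of(post$edge[k, 1]); b <- state_of(post$edge[k, 2])
      if (is.na(a) || is.na(b)) next
      if (a != b) changes <- changes + 1L
    }
    best <- min(best, changes)
  }
  best
}

# a small soluble (hydrophilic) protein with a GYG motif
soluble_gyg <- paste0(strrep("DKE", 15), "GYG", strrep("SDR", 10))

# a membrane protein with two TMs and no filter motif
two_tm_no_motif <- paste0(strrep("D", 10), strrep("I", 22), strrep("DKES", 6),
                          strrep("L", 22), strrep("E", 8))
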