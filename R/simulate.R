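# Synthetic benchmark generator: host channel-paralog families plus a viral
# clade evolving under the piracy or the independent-origin scenario, with
# full ground truth (true tree, planted pore-module coordinates, per-branch
# mutation counts).
#
# Sequence architecture per channel: head | TM1 | pore-helix linker |
# selectivity filter | TM2 | tail. Filter columns evolve at a small
# fraction of the mean rate (conserved); TM columns evolve under the
# replacement model restricted to hydrophobic residues; indels are confined
# to head/linker/tail so the pore architecture survives divergence.

HYDROPHOBIC <- c("I", "L", "V", "F", "A")

#' Scenario configuration for the synthetic benchmark
#'
#' The two scenarios mirror the hypothesis contrast: `"independent"`
#' attaches the viral clade outside the host gene family (viral crown age
#' deeper than host speciation), `"piracy"` nests it inside one host
#' species' paralog lineage at shallow depth (a recent capture).
#'
#' Depths are expected substitutions per site. Host gene trees are built as
#' a paralog duplication tree (crown age `2 * host_speciation_depth`) whose
#' every tip carries a copy of the species tree (crown age
#' `host_speciation_depth`), so duplications predate speciation as in real
#' channel families.
#'
#' @param scenario `"independent"` or `"piracy"`.
#' @param n_host_species,n_paralogs_per_host,n_viral taxon counts.
#' @param host_speciation_depth species-tree crown age.
#' @param viral_divergence_depth viral crown age; must exceed
#'   `host_speciation_depth` for `"independent"` and be below it for
#'   `"piracy"`.
#' @param indel_rate indel events per substitution (in linker regions).
#' @param filter_rate relative substitution rate of filter columns.
#' @param seed integer seed for the run's single random stream.
#' @param architecture list: `head_len`, `tm1_len`, `linker_len`, `filter`
#'   (planted filter string; the default embeds the canonical TxxTxG\[FY\]G
#'   signature), `tm2_len`, `tail_len`.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("independent", "piracy"),
                            n_host_species = 3L, n_paralogs_per_host = 3L,
                            n_viral = 5L,
                            host_speciation_depth = 0.2,
                            viral_divergence_depth = NULL,
                            indel_rate = 0.02, filter_rate = 0.05,
                            seed = 1L, architecture = list()) {
  scenario <- match.arg(scenario)
  if (is.null(viral_divergence_depth)) {
    viral_divergence_depth <- if (scenario == "independent") 0.3
                              else 0.05
  }
  if (host_speciation_depth <= 0 || viral_divergence_depth <= 0) {
    stop("depths must be > 0")
  }
  if (scenario == "independent" &&
      viral_divergence_depth <= host_speciation_depth) {
    stop("independent scenario needs viral_divergence_depth > host_speciation_depth")
  }
  if (scenario == "piracy" &&
      viral_divergence_depth >= host_speciation_depth) {
    stop("piracy scenario needs viral_divergence_depth < host_speciation_depth")
  }
  if (n_host_species < 2L || n_viral < 2L) stop("need >= 2 host species and >= 2 viral taxa")
  arch <- modifyList(list(head_len = 8L, tm1_len = 21L, linker_len = 22L,
                          filter = "TMTTVGYG", tm2_len = 21L, tail_len = 10L),
                     architecture)
  structure(list(scenario = scenario, n_host_species = as.integer(n_host_species),
                 n_paralogs_per_host = as.integer(n_paralogs_per_host),
                 n_viral = as.integer(n_viral),
                 host_speciation_depth = host_speciation_depth,
                 viral_divergence_depth = viral_divergence_depth,
                 indel_rate = indel_rate, filter_rate = filter_rate,
                 seed = as.integer(seed), architecture = arch),
            class = "scenario_config")
}

# pure-birth (Yule) ultrametric crown tree with n >= 2 tips, rescaled to
# the given depth; uses the current RNG stream
yule_tree <- function(n, depth, labels) {
  stopifnot(n >= 2L, length(labels) == n)
  nodes <- list()
  new_node <- function(label = "") {
    nodes[[length(nodes) + 1L]] <<- list(label = label, children = integer(),
                                         blen = 0)
    length(nodes)
  }
  root <- new_node()
  active <- data.frame(parent = c(root, root), start = c(0, 0))
  tsplit <- 0
  while (nrow(active) < n) {
    k <- nrow(active)
    tsplit <- tsplit + rexp(1, k)
    j <- sample.int(k, 1L)
    nid <- new_node()
    nodes[[nid]]$blen <- tsplit - active$start[[j]]
    nodes[[active$parent[[j]]]]$children <-
      c(nodes[[active$parent[[j]]]]$children, nid)
    active <- rbind(active[-j, , drop = FALSE],
                    data.frame(parent = c(nid, nid), start = c(tsplit, tsplit)))
  }
  H <- tsplit + rexp(1, n)
  labs <- labels[sample.int(n)]
  for (j in seq_len(n)) {
    nid <- new_node(labs[[j]])
    nodes[[nid]]$blen <- H - active$start[[j]]
    nodes[[active$parent[[j]]]]$children <-
      c(nodes[[active$parent[[j]]]]$children, nid)
  }
  scale <- depth / H
  to_newick <- function(id) {
    nd <- nodes[[id]]
    body <- if (length(nd$children)) {
      paste0("(", paste(vapply(nd$children, to_newick, character(1)),
                        collapse = ","), ")")
    } else nd$label
    if (id == root) body else paste0(body, ":", format(nd$blen * scale, digits = 12))
  }
  ape::read.tree(text = paste0(to_newick(root), ";"))
}

sim_tree_impl <- function(config) {
  hsd <- config$host_speciation_depth
  species <- paste0("sp", LETTERS[seq_len(config$n_host_species)])
  npar <- config$n_paralogs_per_host
  if (npar >= 2L) {
    # paralog families arise in one ancient duplication burst (star
    # radiation): equal family stems avoid rogue deep lineages that would
    # dominate the gene tree by long-branch effects
    nwk <- paste0("(", paste0("PARALOG", seq_len(npar), ":", 2 * hsd,
                              collapse = ","), ");")
    # graft a species-tree copy onto every paralog tip (newick splicing:
    # robust for tiny trees where edge-matrix surgery is fragile)
    for (p in seq_len(npar)) {
      sp_tree <- yule_tree(config$n_host_species, hsd,
                           paste0(species, "_K", p))
      body <- sub(";$", "", write_newick(sp_tree))
      nwk <- sub(paste0("PARALOG", p, ":"), paste0(body, ":"), nwk,
                 fixed = TRUE)
    }
    host <- ape::read.tree(text = nwk)
  } else {
    host <- yule_tree(config$n_host_species, hsd, paste0(species, "_K1"))
  }
  host_depth <- max(ape::node.depth.edgelength(host))
  viral_labels <- paste0("V", seq_len(config$n_viral))
  if (config$scenario == "independent") {
    vdd <- config$viral_divergence_depth
    vir <- yule_tree(config$n_viral, vdd, viral_labels)
    # generous stem: the hypothesis contrast is a viral lineage clearly
    # separated from the host radiation (long internal edge)
    total <- max(host_depth, vdd) + 0.3
    txt <- paste0("(", sub(";$", "", write_newick(host)), ":",
                  format(total - host_depth, digits = 12),
                  ",", sub(";$", "", write_newick(vir)), ":",
                  format(total - vdd, digits = 12), ");")
    tree <- ape::read.tree(text = txt)
    target_species <- species[1 + (seq_len(config$n_viral) - 1) %%
                                length(species)]
    viral_sources <- setNames(target_species, viral_labels)
  } else {
    # capture into the host lineage with the longest terminal branch: the
    # attachment point and the viral crown must both fit on that branch for
    # the nesting to be phylogenetically identifiable
    term <- host$edge[, 2] <= length(host$tip.label)
    tb_all <- setNames(host$edge.length[term], host$tip.label[host$edge[term, 2]])
    target <- names(sort(tb_all, decreasing = TRUE))[[1]]
    tip <- which(host$tip.label == target)
    k <- which(host$edge[, 2] == tip)
    tb <- host$edge.length[[k]]
    attach_depth <- min(0.5 * tb, 2 * config$viral_divergence_depth)
    v_eff <- min(config$viral_divergence_depth, 0.9 * attach_depth)
    vir <- yule_tree(config$n_viral, v_eff, viral_labels)
    vir$root.edge <- attach_depth - v_eff
    tree <- ape::bind.tree(host, vir, where = tip, position = attach_depth)
    viral_sources <- setNames(rep(sub("_K[0-9]+$", "", target),
                                  config$n_viral), viral_labels)
  }
  tree <- ape::unroot(tree)
  host_ids <- grep("^sp", tree$tip.label, value = TRUE)
  labels <- data.frame(
    id = c(host_ids, viral_labels),
    role = c(rep("host", length(host_ids)), rep("viral", config$n_viral)),
    source = c(sub("_K[0-9]+$", "", host_ids), unname(viral_sources)),
    stringsAsFactors = FALSE)
  list(tree = tree, labels = labels)
}

#' Simulate the scenario's true gene tree
#'
#' @param config a [scenario_config()].
#' @return list with `tree` (unrooted ape `phylo`, branch lengths in
#'   substitutions/site) and `labels` (id, role, source).
#' @export
simulate_tree <- function(config) {
  with_seed(config$seed, sim_tree_impl(config))
}

# simulation models: full replacement model for linkers, restricted
# hydrophobic model for TM columns (rows/cols of the exchangeability matrix
# over {I,L,V,F,A}, frequencies renormalized, mean rate 1)
sim_models <- function() {
  if (is.null(.pkg_cache$sim_models)) {
    wag <- load_wag()
    make <- function(S, freq) {
      freq <- freq / sum(freq)
      Q <- S %*% diag(freq)
      diag(Q) <- 0; diag(Q) <- -rowSums(Q)
      Q <- Q / (-sum(freq * diag(Q)))
      sp <- sqrt(freq)
      B <- diag(sp) %*% Q %*% diag(1 / sp)
      eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
      list(states = rownames(S), freq = freq,
           evec = diag(1 / sp) %*% eig$vectors,
           ivec = t(eig$vectors) %*% diag(sp), eval = eig$values)
    }
    # loop/linker columns are solvent-exposed: keep the full alphabet but
    # down-weight strongly hydrophobic residues so loops stay loop-like and
    # the two TMs remain separable in hydropathy space
    loop_freq <- wag$freq
    loop_freq[c("I", "L", "V", "F", "M", "C", "W")] <-
      0.2 * loop_freq[c("I", "L", "V", "F", "M", "C", "W")]
    .pkg_cache$sim_models <- list(
      full = make(wag$S, wag$freq),
      loop = make(wag$S, loop_freq),
      tm = make(wag$S[HYDROPHOBIC, HYDROPHOBIC], wag$freq[HYDROPHOBIC])
    )
  }
  .pkg_cache$sim_models
}

sim_pmatrix <- function(m, t) {
  P <- m$evec %*% diag(exp(m$eval * t)) %*% m$ivec
  P[P < 0] <- 0
  P / rowSums(P)
}

draw_from <- function(m, n) sample(m$states, n, replace = TRUE, prob = m$freq)

root_blocks <- function(config) {
  arch <- config$architecture
  full <- sim_models()$loop; tm <- sim_models()$tm
  linker <- draw_from(full, arch$linker_len)
  if (arch$linker_len >= 6L) {
    linker[[ceiling(arch$linker_len / 2)]] <- "W" # pore-helix aromatic
  }
  mk <- function(chars, class) list(chars = chars, class = class)
  blocks <- list(
    head = mk(draw_from(full, arch$head_len), "linker"),
    tm1 = mk(draw_from(tm, arch$tm1_len), "tm"),
    linker = mk(linker, "linker"),
    filter = mk(strsplit(arch$filter, "")[[1]], "filter"),
    tm2 = mk(draw_from(tm, arch$tm2_len), "tm"),
    tail = mk(draw_from(full, arch$tail_len), "linker")
  )
  blocks
}

# substitutions on one block for branch length t; returns chars + change idx
evolve_block <- function(chars, class, t, config, col_ids, changes_env,
                         core = NULL) {
  models <- sim_models()
  m <- switch(class, tm = models$tm, linker = models$loop, models$full)
  rate <- if (class == "filter") config$filter_rate else 1
  P <- sim_pmatrix(m, t * rate)
  idx <- match(chars, m$states)
  out <- chars
  for (s in unique(idx[!is.na(idx)])) {
    which_s <- which(idx == s)
    out[which_s] <- sample(m$states, length(which_s), replace = TRUE,
                           prob = P[s, ])
  }
  if (!is.null(core)) {
    # the core G-x-G selectivity signature is under absolute purifying
    # selection (channels that lose it are nonfunctional): revert changes
    # at the G anchors and any middle state outside {Y, F, L}
    out[core[c(1L, 3L)]] <- chars[core[c(1L, 3L)]]
    if (!out[core[2L]] %in% c("Y", "F", "L")) out[core[2L]] <- chars[core[2L]]
  }
  # characters outside the block model (e.g. filter residues under the
  # hydrophobic model never arise; filter block uses the full model)
  changed <- which(out != chars)
  for (ci in col_ids[changed]) {
    key <- as.character(ci)
    assign(key, get0(key, envir = changes_env, ifnotfound = 0) + 1,
           envir = changes_env)
  }
  list(chars = out, n_changes = length(changed))
}

apply_indels <- function(blocks, t, config, next_col_id, changes_env) {
  linker_idx <- which(vapply(blocks, function(b) b$class == "linker",
                             logical(1)))
  n_linker <- sum(vapply(blocks[linker_idx], function(b) length(b$chars),
                         integer(1)))
  if (n_linker == 0L || config$indel_rate <= 0) {
    return(list(blocks = blocks, next_col_id = next_col_id))
  }
  n_events <- rpois(1, config$indel_rate * t * n_linker)
  full <- sim_models()$loop
  for (e in seq_len(n_events)) {
    lens <- vapply(blocks[linker_idx], function(b) length(b$chars), integer(1))
    if (sum(lens) == 0L) break
    bi <- linker_idx[[sample.int(length(linker_idx), 1L,
                                 prob = pmax(lens, 1e-9))]]
    blen <- length(blocks[[bi]]$chars)
    len <- rgeom(1, 1 / 3) + 1L
    if (runif(1) < 0.5 && blen > len) { # deletion (keep blocks non-empty)
      pos <- sample.int(blen - len + 1L, 1L)
      keep <- setdiff(seq_len(blen), pos:(pos + len - 1L))
      blocks[[bi]]$chars <- blocks[[bi]]$chars[keep]
      blocks[[bi]]$ids <- blocks[[bi]]$ids[keep]
    } else { # insertion
      pos <- sample.int(blen + 1L, 1L) - 1L
      ins <- draw_from(full, len)
      ins_ids <- next_col_id + seq_len(len) - 1L
      next_col_id <- next_col_id + len
      blocks[[bi]]$chars <- append(blocks[[bi]]$chars, ins, after = pos)
      blocks[[bi]]$ids <- append(blocks[[bi]]$ids, ins_ids, after = pos)
    }
  }
  list(blocks = blocks, next_col_id = next_col_id)
}

evolve_impl <- function(tree, config) {
  blocks <- root_blocks(config)
  # column ids for mutation bookkeeping
  cid <- 0L
  for (b in names(blocks)) {
    blocks[[b]]$ids <- cid + seq_along(blocks[[b]]$chars)
    cid <- cid + length(blocks[[b]]$chars)
  }
  changes_env <- new.env(parent = emptyenv())
  # core selectivity signature (G-[YFL]-G) position within the filter block
  filt <- paste(blocks$filter$chars, collapse = "")
  core_at <- regexpr("G[YFL]G[^G]*$", filt)
  core_idx <- if (core_at > 0) as.integer(core_at) + 0:2 else NULL
  ntip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[[1]]
  node_blocks <- vector("list", ntip + tree$Nnode)
  node_blocks[[root]] <- blocks
  branch_changes <- data.frame(parent = integer(), child = integer(),
                               changes = integer())
  pre <- ape::reorder.phylo(tree, "cladewise")
  next_col <- cid + 1L
  for (k in seq_len(nrow(pre$edge))) {
    par <- pre$edge[k, 1]; child <- pre$edge[k, 2]
    t <- pre$edge.length[[k]]
    bl <- node_blocks[[par]]
    nch <- 0L
    for (b in names(bl)) {
      ev <- evolve_block(bl[[b]]$chars, bl[[b]]$class, t, config,
                         bl[[b]]$ids, changes_env,
                         core = if (b == "filter") core_idx)
      bl[[b]]$chars <- ev$chars
      nch <- nch + ev$n_changes
    }
    ind <- apply_indels(bl, t, config, next_col, changes_env)
    bl <- ind$blocks; next_col <- ind$next_col_id
    node_blocks[[child]] <- bl
    branch_changes <- rbind(branch_changes,
                            data.frame(parent = par, child = child,
                                       changes = nch))
  }
  coords <- list(); seqs <- character(ntip)
  for (tp in seq_len(ntip)) {
    bl <- node_blocks[[tp]]
    lens <- vapply(bl, function(b) length(b$chars), integer(1))
    off <- cumsum(c(0, lens))
    names(off) <- c(names(bl), "end")
    seqs[[tp]] <- paste(unlist(lapply(bl, `[[`, "chars")), collapse = "")
    coords[[tp]] <- data.frame(
      id = tree$tip.label[[tp]],
      tm1_start = off[["tm1"]] + 1L, tm1_end = off[["linker"]],
      filter_start = off[["filter"]] + 1L, filter_end = off[["tm2"]],
      tm2_start = off[["tm2"]] + 1L, tm2_end = off[["tail"]],
      stringsAsFactors = FALSE)
  }
  coords <- do.call(rbind, coords)
  coords$module_start <- coords$tm1_start
  coords$module_end <- coords$tm2_end
  list(seqs = setNames(seqs, tree$tip.label), coords = coords,
       branch_changes = branch_changes,
       column_changes = unlist(as.list(changes_env)))
}

#' Evolve sequences along a scenario tree
#'
#' @param tree result of [simulate_tree()] (or a `phylo` with branch
#'   lengths plus a labels `data.frame`).
#' @param config a [scenario_config()].
#' @return list: `records` (sequence `data.frame` with roles), `truth`
#'   (true tree, planted coordinates, per-branch change counts, per-column
#'   change counts).
#' @export
evolve_sequences <- function(tree, config) {
  sim <- with_seed(config$seed + 1L, evolve_impl(tree$tree, config))
  records <- seq_records(names(sim$seqs), sim$seqs)
  records <- assign_roles(records, tree$labels)
  list(records = records,
       truth = list(tree = tree$tree, labels = tree$labels,
                    coords = sim$coords,
                    branch_changes = sim$branch_changes,
                    column_changes = sim$column_changes))
}

#' Generate a complete in-memory benchmark
#'
#' One call producing the scenario tree, sequences and ground truth from a
#' single seeded random stream.
#'
#' @param config a [scenario_config()].
#' @return as [evolve_sequences()].
#' @export
simulate_benchmark <- function(config) {
  with_seed(config$seed, {
    tr <- sim_tree_impl(config)
    sim <- evolve_impl(tr$tree, config)
    records <- seq_records(names(sim$seqs), sim$seqs)
    records <- assign_roles(records, tr$labels)
    list(records = records,
         truth = list(tree = tr$tree, labels = tr$labels,
                      coords = sim$coords,
                      branch_changes = sim$branch_changes,
                      column_changes = sim$column_changes))
  })
}

#' Write a benchmark fixture directory
#'
#' Writes `sequences.fasta`, `labels.tsv`, `truth.nwk`, `truth.json` and a
#' `README.txt` recording the configuration and seed.
#'
#' @param config a [scenario_config()].
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
make_benchmark <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("directory not empty (use force = TRUE): ", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bench <- simulate_benchmark(config)
  write_fasta(bench$records, file.path(dir, "sequences.fasta"))
  write_label_map(bench$truth$labels, file.path(dir, "labels.tsv"))
  writeLines(write_newick(bench$truth$tree), file.path(dir, "truth.nwk"))
  jsonlite::write_json(
    list(schema = "porephylo-benchmark-1",
         config = unclass(config),
         coords = bench$truth$coords,
         branch_changes = bench$truth$branch_changes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c("porephylo synthetic benchmark",
               paste0("scenario: ", config$scenario),
               paste0("seed: ", config$seed),
               "files: sequences.fasta labels.tsv truth.nwk truth.json"),
             file.path(dir, "README.txt"))
  invisible(dir)
}
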