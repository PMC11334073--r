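# Independent oracles and fixture generators used across the suite.
# The brute-force DTL oracle enumerates full gene-node -> species-node
# mappings and prices events from first principles (no in/out tables),
# so it shares no machinery with the dynamic program it checks.

# descendant / edge-distance matrices straight off the parent pointers
bf_species_index <- function(sp) {
  n <- sp$n_nodes
  desc <- matrix(FALSE, n, n)   # desc[a, d]: d in subtree of a (incl. a)
  ed <- matrix(Inf, n, n)       # edges from a down to descendant d
  for (v in seq_len(n)) {
    desc[v, v] <- TRUE; ed[v, v] <- 0
    p <- v; k <- 0
    while (sp$parent[p] != 0L) {
      k <- k + 1; p <- sp$parent[p]
      desc[p, v] <- TRUE; ed[p, v] <- k
    }
  }
  list(desc = desc, ed = ed)
}

# min event cost for a gene node mapped at s whose children map at (u, v):
# speciation (children under distinct child subtrees, one loss per skipped
# branch), duplication (both under s), or transfer (one under s, one
# incomparable to s, landing exactly)
bf_event_tensor <- function(sp, costs) {
  idx <- bf_species_index(sp)
  n <- sp$n_nodes
  E <- array(Inf, c(n, n, n))
  for (s in seq_len(n)) {
    kids <- sp$children[[s]]
    for (u in seq_len(n)) for (v in seq_len(n)) {
      best <- Inf
      if (length(kids) == 2) {
        c1 <- kids[1]; c2 <- kids[2]
        if (idx$desc[c1, u] && idx$desc[c2, v])
          best <- min(best, costs$loss * (idx$ed[c1, u] + idx$ed[c2, v]))
        if (idx$desc[c1, v] && idx$desc[c2, u])
          best <- min(best, costs$loss * (idx$ed[c1, v] + idx$ed[c2, u]))
      }
      if (idx$desc[s, u] && idx$desc[s, v])
        best <- min(best, costs$dup + costs$loss * (idx$ed[s, u] + idx$ed[s, v]))
      inc_su <- !idx$desc[s, u] && !idx$desc[u, s]
      inc_sv <- !idx$desc[s, v] && !idx$desc[v, s]
      if (idx$desc[s, u] && inc_sv)
        best <- min(best, costs$transfer + costs$loss * idx$ed[s, u])
      if (idx$desc[s, v] && inc_su)
        best <- min(best, costs$transfer + costs$loss * idx$ed[s, v])
      E[s, u, v] <- best
    }
  }
  E
}

# exhaustive minimum over all mappings of internal gene nodes
brute_force_dtl <- function(gene, species, costs) {
  E <- bf_event_tensor(species, costs)
  internals <- gene$postorder[gene$postorder > gene$n_tips]
  leaf_map <- match(gene$genome,
                    species$node_name[seq_len(species$n_tips)])
  nS <- species$n_nodes
  sigma <- as.matrix(expand.grid(rep(list(seq_len(nS)), length(internals))))
  colnames(sigma) <- as.character(internals)
  smap <- function(node) {
    if (node <= gene$n_tips) rep(leaf_map[node], nrow(sigma))
    else sigma[, as.character(node)]
  }
  total <- 0
  for (g in internals) {
    ch <- gene$children[[g]]
    total <- total + E[cbind(smap(g), smap(ch[1]), smap(ch[2]))]
  }
  min(total)
}

# full scenario enumeration for tiny instances (<= 3 internal gene nodes):
# every (mapping, per-node event label) combination achieving the optimum
bf_scenarios <- function(gene, species, costs) {
  idx <- bf_species_index(species)
  internals <- gene$postorder[gene$postorder > gene$n_tips]
  stopifnot(length(internals) <= 3)
  leaf_map <- match(gene$genome,
                    species$node_name[seq_len(species$n_tips)])
  nS <- species$n_nodes
  node_options <- function(g, s, u_node, v_node, u, v) {
    # all priced event labels for gene node g at s, children at u, v
    opts <- list()
    kids <- species$children[[s]]
    if (length(kids) == 2) {
      for (sides in list(c(1, 2), c(2, 1))) {
        ca <- kids[sides[1]]; cb <- kids[sides[2]]
        if (idx$desc[ca, u] && idx$desc[cb, v])
          opts <- c(opts, list(list(ev = "speciation",
                                    cost = costs$loss * (idx$ed[ca, u] + idx$ed[cb, v]),
                                    losses = idx$ed[ca, u] + idx$ed[cb, v])))
      }
    }
    if (idx$desc[s, u] && idx$desc[s, v])
      opts <- c(opts, list(list(ev = "duplication",
                                cost = costs$dup + costs$loss * (idx$ed[s, u] + idx$ed[s, v]),
                                losses = idx$ed[s, u] + idx$ed[s, v])))
    inc <- function(a, b) !idx$desc[a, b] && !idx$desc[b, a]
    if (idx$desc[s, u] && inc(s, v))
      opts <- c(opts, list(list(ev = "transfer", donor = s, recipient = v,
                                cost = costs$transfer + costs$loss * idx$ed[s, u],
                                losses = idx$ed[s, u])))
    if (idx$desc[s, v] && inc(s, u))
      opts <- c(opts, list(list(ev = "transfer", donor = s, recipient = u,
                                cost = costs$transfer + costs$loss * idx$ed[s, v],
                                losses = idx$ed[s, v])))
    opts
  }
  sigma_grid <- as.matrix(expand.grid(rep(list(seq_len(nS)),
                                          length(internals))))
  colnames(sigma_grid) <- as.character(internals)
  scen <- list()
  for (r in seq_len(nrow(sigma_grid))) {
    sig <- sigma_grid[r, ]
    mapped <- function(node) {
      if (node <= gene$n_tips) leaf_map[node] else sig[[as.character(node)]]
    }
    per_node <- lapply(internals, function(g) {
      ch <- gene$children[[g]]
      node_options(g, mapped(g), ch[1], ch[2], mapped(ch[1]), mapped(ch[2]))
    })
    if (any(lengths(per_node) == 0)) next
    combos <- expand.grid(lapply(per_node, seq_along))
    for (ci in seq_len(nrow(combos))) {
      labs <- lapply(seq_along(internals), function(i)
        per_node[[i]][[combos[ci, i]]])
      scen[[length(scen) + 1L]] <- list(
        sigma = sig, labels = labs,
        cost = sum(vapply(labs, `[[`, 0, "cost")),
        n_transfer = sum(vapply(labs, function(l) l$ev == "transfer", TRUE)),
        n_dup = sum(vapply(labs, function(l) l$ev == "duplication", TRUE)),
        n_loss = sum(vapply(labs, `[[`, 0, "losses")))
    }
  }
  costs_all <- vapply(scen, `[[`, 0, "cost")
  list(opt = min(costs_all),
       optimal = scen[abs(costs_all - min(costs_all)) < 1e-9])
}

# literal re-implementation of the RED recursion on a distance matrix
# (phangorn descendants + ape dist.nodes; no shared code with compute_red)
red_oracle <- function(tree) {
  phy <- tree$phylo
  dm <- ape::dist.nodes(phy)
  n_tips <- length(phy$tip.label)
  n <- n_tips + phy$Nnode
  parent <- integer(n); parent[phy$edge[, 2]] <- phy$edge[, 1]
  bl <- numeric(n); bl[phy$edge[, 2]] <- phy$edge.length
  red <- rep(NA_real_, n)
  root <- n_tips + 1L
  red[root] <- 0
  todo <- phy$edge[order(dm[root, phy$edge[, 2]]), 2]  # parents first
  for (v in todo) {
    if (v <= n_tips) { red[v] <- 1; next }
    tips <- unlist(phangorn::Descendants(phy, v, "tips"))
    u <- mean(dm[parent[v], tips])
    red[v] <- red[parent[v]] + (bl[v] / u) * (1 - red[parent[v]])
  }
  red
}

# random reconciliation instance: small species tree plus a gene tree
# whose leaves sample species genomes with replacement
random_instance <- function(max_species = 6, max_gene = 6) {
  ns <- sample(3:max_species, 1)
  sp_phy <- ape::rtree(ns, tip.label = LETTERS[seq_len(ns)])
  species <- as_dtl_tree(sp_phy, "species")
  ng <- sample(2:max_gene, 1)
  g_phy <- ape::rtree(ng)
  genomes <- sample(LETTERS[seq_len(ns)], ng, replace = TRUE)
  g_phy$tip.label <- paste0(genomes, "|g", seq_len(ng))
  g_phy$edge.length <- NULL
  gene <- suppressWarnings(as_dtl_tree(g_phy, "gene"))
  costs <- cost_scheme(dup = sample(1:5, 1), transfer = sample(1:5, 1),
                       loss = sample(1:3, 1))
  list(species = species, gene = gene, costs = costs)
}

balanced_species <- function(n_tips = 16, bl = 1) {
  phy <- ape::stree(n_tips, type = "balanced")
  phy$tip.label <- paste0("G", seq_len(n_tips))
  phy$edge.length <- rep(bl, nrow(phy$edge))
  as_dtl_tree(phy, "species")
}

coal_species <- function(n_tips = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_dtl_tree(ape::rcoal(n_tips, tip.label = paste0("G", seq_len(n_tips))),
              "species")
}

# species (( A,B ),C) with unit-ish lengths, used by several worked cases
abc_species <- function() read_newick("((A:1,B:1):1,C:2);", "species")

gene_from_newick <- function(text) suppressWarnings(read_newick(text, "gene"))

fixture <- function(name) {
  path <- system.file("extdata", name, package = "dtlrecon")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
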