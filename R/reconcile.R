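#' Event costs for parsimony DTL reconciliation
#'
#' @param dup,transfer,loss positive event costs. The default 3:3:1 is
#'   the grid center used throughout the package.
#' @return list of class `cost_scheme`.
#' @export
cost_scheme <- function(dup = 3, transfer = 3, loss = 1) {
  stopifnot(dup > 0, transfer > 0, loss > 0)
  structure(list(dup = dup, transfer = transfer, loss = loss),
            class = "cost_scheme")
}

#' @export
format.cost_scheme <- function(x, ...)
  sprintf("D/T/L=%g:%g:%g", x$dup, x$transfer, x$loss)

# precomputed species-side structures shared across families
species_index <- function(species) {
  anc <- ancestor_matrix(species)
  n <- species$n_nodes
  list(anc = anc,
       incomparable = lapply(seq_len(n), function(s)
         which(!anc[s, ] & !anc[, s] & seq_len(n) != s)),
       internal = which(lengths(species$children) == 2L),
       post = species$postorder,
       pre = rev(species$postorder))
}

#' Minimum-cost undated DTL reconciliation (dynamic program)
#'
#' Fills the standard undated duplication-transfer-loss tables for a
#' rooted binary gene tree against a rooted binary species tree:
#' `c(g,s)` is the minimum cost of the gene subtree at `g` with `g`
#' mapped to species node `s`; `in(g,s)` relaxes the mapping to any node
#' in the subtree of `s`, paying one loss per skipped branch; `out(g,s)`
#' is the best mapping at a node incomparable to `s` (the admissible
#' transfer recipients of the undated model). Internal gene nodes choose
#' the cheapest of speciation, duplication (`cost_D + in + in` at `s`),
#' or transfer (`cost_T` plus one child in, one child out). The optimum
#' is `min_s c(root, s)`; origination is the (cost-free) species mapping
#' of the gene root.
#'
#' @param gene a `gene_tree` whose leaf genomes all occur among the
#'   species leaves.
#' @param species a `species_tree`.
#' @param costs a [cost_scheme()].
#' @param sp_idx optional precomputed [species_index] (internal reuse).
#' @return object of class `dtl_dp`: the tables (`C`, `IN`, `OUT`, `M`),
#'   `opt_cost`, `root_candidates`, and the inputs.
#' @export
reconcile_min_cost <- function(gene, species, costs = cost_scheme(),
                               sp_idx = NULL) {
  stopifnot(inherits(gene, "gene_tree"), inherits(species, "species_tree"),
            inherits(costs, "cost_scheme"))
  if (is.null(sp_idx)) sp_idx <- species_index(species)
  nS <- species$n_nodes; nG <- gene$n_nodes
  leaf_map <- match(gene$genome, species$node_name[seq_len(species$n_tips)])
  if (anyNA(leaf_map)) {
    bad <- gene$phylo$tip.label[is.na(leaf_map)][1]
    stop("gene leaf not resolvable to a species leaf: ", bad, call. = FALSE)
  }

  D <- costs$dup; Tc <- costs$transfer; L <- costs$loss
  C <- matrix(Inf, nG, nS); IN <- matrix(Inf, nG, nS)
  OUT <- matrix(Inf, nG, nS); M <- matrix(Inf, nG, nS)

  for (g in gene$postorder) {
    if (is_leaf(gene, g)) {
      C[g, leaf_map[g]] <- 0
    } else {
      ch <- gene$children[[g]]
      in1 <- IN[ch[1], ]; in2 <- IN[ch[2], ]
      out1 <- OUT[ch[1], ]; out2 <- OUT[ch[2], ]
      cg <- rep(Inf, nS)
      for (s in sp_idx$internal) {
        sc <- species$children[[s]]
        cg[s] <- min(in1[sc[1]] + in2[sc[2]], in1[sc[2]] + in2[sc[1]])
      }
      cg <- pmin(cg, D + in1 + in2,
                 Tc + pmin(in1 + out2, in2 + out1))
      C[g, ] <- cg
    }
    # IN / M by species postorder, OUT by preorder
    ing <- C[g, ]; mg <- C[g, ]
    for (s in sp_idx$post) {
      if (!is_leaf(species, s)) {
        sc <- species$children[[s]]
        ing[s] <- min(ing[s], ing[sc[1]] + L, ing[sc[2]] + L)
        mg[s] <- min(mg[s], mg[sc[1]], mg[sc[2]])
      }
    }
    outg <- rep(Inf, nS)
    for (s in sp_idx$pre) {
      if (!is_leaf(species, s)) {
        sc <- species$children[[s]]
        outg[sc[1]] <- min(outg[s], mg[sc[2]])
        outg[sc[2]] <- min(outg[s], mg[sc[1]])
      }
    }
    IN[g, ] <- ing; M[g, ] <- mg; OUT[g, ] <- outg
  }

  groot <- gene$root
  opt <- min(C[groot, ])
  structure(list(C = C, IN = IN, OUT = OUT, M = M,
                 opt_cost = opt,
                 root_candidates = which(C[groot, ] <= opt + dp_eps(opt)),
                 gene = gene, species = species, costs = costs,
                 sp_idx = sp_idx, leaf_map = leaf_map),
            class = "dtl_dp")
}

dp_eps <- function(x) 1e-9 * max(1, abs(x[is.finite(x)]))

#' @export
print.dtl_dp <- function(x, ...) {
  cat(sprintf("<dtl_dp> optimum %g (%s), %d gene leaves vs %d species leaves\n",
              x$opt_cost, format(x$costs), x$gene$n_tips, x$species$n_tips))
  invisible(x)
}

#' Sample one reconciliation from the DP tables
#'
#' Traceback through the dynamic program choosing uniformly at random
#' among co-optimal alternatives at every decision point: gene-root
#' placement, event kind at each gene node, child-side assignment at
#' speciations, loss-path endpoints, and transfer recipients. Losses are
#' materialized as one explicit event per skipped species branch. The
#' emitted event multiset always re-prices to the DP optimum.
#'
#' @param dp a `dtl_dp` from [reconcile_min_cost()].
#' @return object of class `reconciliation`: `mapping` (gene node ->
#'   species node), `events` (data.frame kind/node/recipient; kinds
#'   speciation, duplication, transfer, loss, origination), `total_cost`,
#'   and per-branch accounting (`gains`, `losses`, `copies`,
#'   `vertical_passages` vectors over species nodes).
#' @export
sample_reconciliation <- function(dp) {
  gene <- dp$gene; species <- dp$species
  D <- dp$costs$dup; Tc <- dp$costs$transfer; L <- dp$costs$loss
  C <- dp$C; IN <- dp$IN; OUT <- dp$OUT
  eps <- dp_eps(dp$opt_cost)

  kind <- character(0); node <- integer(0); recip <- integer(0)
  mapping <- integer(gene$n_nodes)
  add_ev <- function(k, s, r = NA_integer_) {
    kind[[length(kind) + 1L]] <<- k
    node[[length(node) + 1L]] <<- s
    recip[[length(recip) + 1L]] <<- r
  }
  pick <- function(idx) idx[sample.int(length(idx), 1L)]

  tb_exact <- function(g, s) {
    mapping[g] <<- s
    if (is_leaf(gene, g)) return(invisible())
    ch <- gene$children[[g]]
    g1 <- ch[1]; g2 <- ch[2]
    target <- C[g, s]
    opts <- list()
    if (!is_leaf(species, s)) {
      sc <- species$children[[s]]
      if (IN[g1, sc[1]] + IN[g2, sc[2]] <= target + eps)
        opts <- c(opts, list(list(ev = "speciation", a = sc[1], b = sc[2])))
      if (IN[g1, sc[2]] + IN[g2, sc[1]] <= target + eps)
        opts <- c(opts, list(list(ev = "speciation", a = sc[2], b = sc[1])))
    }
    if (D + IN[g1, s] + IN[g2, s] <= target + eps)
      opts <- c(opts, list(list(ev = "duplication")))
    if (Tc + IN[g1, s] + OUT[g2, s] <= target + eps)
      opts <- c(opts, list(list(ev = "transfer", stay = g1, move = g2)))
    if (Tc + IN[g2, s] + OUT[g1, s] <= target + eps)
      opts <- c(opts, list(list(ev = "transfer", stay = g2, move = g1)))
    o <- opts[[pick(seq_along(opts))]]
    if (o$ev == "speciation") {
      add_ev("speciation", s)
      tb_in(g1, o$a); tb_in(g2, o$b)
    } else if (o$ev == "duplication") {
      add_ev("duplication", s)
      tb_in(g1, s); tb_in(g2, s)
    } else {
      sprime <- tb_pick_out(o$move, s)
      add_ev("transfer", s, sprime)
      tb_in(o$stay, s)
      tb_exact(o$move, sprime)
    }
  }

  tb_in <- function(g, s) {
    repeat {
      val <- IN[g, s]
      opts <- list()
      if (C[g, s] <= val + eps) opts <- c(opts, list(list(stay = TRUE)))
      if (!is_leaf(species, s)) {
        sc <- species$children[[s]]
        if (IN[g, sc[1]] + L <= val + eps)
          opts <- c(opts, list(list(stay = FALSE, into = sc[1], lost = sc[2])))
        if (IN[g, sc[2]] + L <= val + eps)
          opts <- c(opts, list(list(stay = FALSE, into = sc[2], lost = sc[1])))
      }
      o <- opts[[pick(seq_along(opts))]]
      if (isTRUE(o$stay)) { tb_exact(g, s); return(invisible()) }
      add_ev("loss", o$lost)
      s <- o$into
    }
  }

  tb_pick_out <- function(g, s) {
    cand <- dp$sp_idx$incomparable[[s]]
    hit <- cand[C[g, cand] <= OUT[g, s] + eps]
    pick(hit)
  }

  s0 <- pick(dp$root_candidates)
  add_ev("origination", s0)
  tb_exact(gene$root, s0)

  events <- data.frame(kind = kind, node = node, recipient = recip,
                       stringsAsFactors = FALSE)
  acct <- branch_accounting(events, species)
  structure(c(list(mapping = mapping, events = events,
                   total_cost = dp$opt_cost), acct),
            class = "reconciliation")
}

# per-branch gains/losses/copies/passages from one event list
branch_accounting <- function(events, species) {
  n <- species$n_nodes
  gains_o <- tabulate(events$node[events$kind == "origination"], nbins = n)
  gains_d <- tabulate(events$node[events$kind == "duplication"], nbins = n)
  gains_t <- tabulate(events$recipient[events$kind == "transfer"], nbins = n)
  losses <- tabulate(events$node[events$kind == "loss"], nbins = n)
  gains <- gains_o + gains_d + gains_t
  copies <- numeric(n)
  for (v in rev(species$postorder)) {   # preorder replay
    p <- species$parent[v]
    copies[v] <- (if (p == 0L) 0 else copies[p]) + gains[v] - losses[v]
  }
  vert <- ifelse(seq_len(n) > species$n_tips, copies, 0)
  list(gains_origination = gains_o, gains_duplication = gains_d,
       gains_transfer = gains_t, losses = losses, copies = copies,
       vertical_passages = vert)
}

# re-price an event list under a cost scheme (sanity/pricing identity)
price_events <- function(events, costs) {
  costs$dup * sum(events$kind == "duplication") +
    costs$transfer * sum(events$kind == "transfer") +
    costs$loss * sum(events$kind == "loss")
}

#' Reconcile one family over repeated sampling trials
#'
#' Runs `n_trials` traceback samplings of the co-optimal reconciliation
#' space and aggregates: per species branch and event kind the
#' across-trial median, per donor-recipient pair the median transfer
#' count, and per-trial family totals (with means and medians). Medians
#' over co-optimal samples are the aggregation unit; summing raw
#' (possibly fractional) medians across families and rounding only after
#' the sum is the downstream convention.
#'
#' @param gene,species,costs as in [reconcile_min_cost()].
#' @param n_trials number of sampled reconciliations (default 100).
#' @param seed optional seed for this family's trials.
#' @param sp_idx optional precomputed species index.
#' @param family family identifier carried into the output tables.
#' @return object of class `dtl_trials`: `per_branch` (data.frame of
#'   across-trial medians per branch), `transfer_pairs` (donor, recipient,
#'   median_count), `totals` (mean/median per event kind),
#'   `totals_by_trial` (matrix), `opt_cost`, `n_trials`.
#' @export
reconcile_family_trials <- function(gene, species, costs = cost_scheme(),
                                    n_trials = 100L, seed = NULL,
                                    sp_idx = NULL, family = "fam1") {
  if (!is.null(seed)) set.seed(seed)
  dp <- reconcile_min_cost(gene, species, costs, sp_idx = sp_idx)
  n <- species$n_nodes
  cols <- c("gains_origination", "gains_duplication", "gains_transfer",
            "losses", "vertical_passages", "copies")
  arr <- array(0, dim = c(n, length(cols), n_trials),
               dimnames = list(NULL, cols, NULL))
  totals <- matrix(0, n_trials, 5,
                   dimnames = list(NULL, c("origination", "duplication",
                                           "transfer", "loss",
                                           "vertical_passages")))
  pair_counts <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    r <- sample_reconciliation(dp)
    for (cl in cols) arr[, cl, t] <- r[[cl]]
    totals[t, ] <- c(sum(r$gains_origination), sum(r$gains_duplication),
                     sum(r$gains_transfer), sum(r$losses),
                     sum(r$vertical_passages))
    tr <- r$events[r$events$kind == "transfer", , drop = FALSE]
    if (nrow(tr)) {
      key <- paste(tr$node, tr$recipient, sep = ":")
      pair_counts[[t]] <- table(key)
    }
  }
  med <- apply(arr, c(1, 2), stats::median)
  per_branch <- data.frame(family = family, node = seq_len(n),
                           node_name = species$node_name, med,
                           stringsAsFactors = FALSE)

  all_keys <- unique(unlist(lapply(pair_counts, names)))
  transfer_pairs <- if (length(all_keys)) {
    mat <- matrix(0, length(all_keys), n_trials,
                  dimnames = list(all_keys, NULL))
    for (t in seq_len(n_trials))
      if (!is.null(pair_counts[[t]]))
        mat[names(pair_counts[[t]]), t] <- as.numeric(pair_counts[[t]])
    ks <- strsplit(all_keys, ":", fixed = TRUE)
    data.frame(family = family,
               donor = as.integer(vapply(ks, `[`, "", 1)),
               recipient = as.integer(vapply(ks, `[`, "", 2)),
               median_count = apply(mat, 1, stats::median),
               mean_count = rowMeans(mat),
               stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(0), donor = integer(0),
               recipient = integer(0), median_count = numeric(0),
               mean_count = numeric(0))
  }

  structure(list(family = family, per_branch = per_branch,
                 transfer_pairs = transfer_pairs,
                 totals = rbind(mean = colMeans(totals),
                                median = apply(totals, 2, stats::median)),
                 totals_by_trial = totals,
                 opt_cost = dp$opt_cost, n_trials = n_trials,
                 costs = costs),
            class = "dtl_trials")
}

#' @export
print.dtl_trials <- function(x, ...) {
  cat(sprintf("<dtl_trials> %s: cost %g over %d trials (%s)\n",
              x$family, x$opt_cost, x$n_trials, format(x$costs)))
  invisible(x)
}

#' Reconcile a set of families
#'
#' @param genes named list of `gene_tree` objects (or a `sim_dataset`,
#'   whose eligible families are used).
#' @param species a `species_tree`.
#' @param costs a [cost_scheme()].
#' @param n_trials sampling trials per family.
#' @param seed integer; per-family substream seeds are derived from it so
#'   any family is independently reproducible.
#' @return list of `dtl_trials`, one per family.
#' @export
reconcile_dataset <- function(genes, species, costs = cost_scheme(),
                              n_trials = 100L, seed = 1L) {
  genes <- dataset_gene_trees(genes)
  sp_idx <- species_index(species)
  out <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    out[[k]] <- reconcile_family_trials(
      genes[[k]], species, costs, n_trials = n_trials,
      seed = substream_seed(seed, k), sp_idx = sp_idx,
      family = names(genes)[k])
  }
  names(out) <- names(genes)
  out
}

dataset_gene_trees <- function(genes) {
  if (inherits(genes, "sim_dataset")) {
    fams <- genes$families[genes$eligible]
    gt <- lapply(fams, `[[`, "gene")
    names(gt) <- vapply(fams, `[[`, "", "family")
    return(gt)
  }
  stopifnot(is.list(genes), length(genes) >= 1)
  if (is.null(names(genes))) names(genes) <- paste0("fam", seq_along(genes))
  genes
}

# deterministic substream seeds below 2^31
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483629)
}

#' Run a grid of cost schemes over a family set
#'
#' One summed event table per cost scheme: per-family trial medians are
#' summed across families, with integer rounding applied only after the
#' sum. Used to examine sensitivity of the inferred transfer level to
#' the assumed costs.
#'
#' @param genes list of gene trees or a `sim_dataset`.
#' @param species a `species_tree`.
#' @param grid list of [cost_scheme()]s; the default is a small grid
#'   centered on D/T/L = 3:3:1.
#' @param n_trials,seed as in [reconcile_dataset()].
#' @return data.frame: one row per scheme with summed (then rounded)
#'   origination/duplication/transfer/loss totals.
#' @export
cost_grid_run <- function(genes, species, grid = default_cost_grid(),
                          n_trials = 100L, seed = 1L) {
  stopifnot(length(grid) >= 1)
  rows <- lapply(seq_along(grid), function(i) {
    trials <- reconcile_dataset(genes, species, grid[[i]],
                                n_trials = n_trials,
                                seed = substream_seed(seed, 1000L + i))
    sums <- Reduce(`+`, lapply(trials, function(tr) tr$totals["median", ]))
    data.frame(scheme = format(grid[[i]]),
               cost_D = grid[[i]]$dup, cost_T = grid[[i]]$transfer,
               cost_L = grid[[i]]$loss,
               origination = round(sums[["origination"]]),
               duplication = round(sums[["duplication"]]),
               transfer = round(sums[["transfer"]]),
               loss = round(sums[["loss"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname cost_grid_run
#' @export
default_cost_grid <- function() {
  list(cost_scheme(3, 3, 1), cost_scheme(2, 3, 1), cost_scheme(3, 2, 1),
       cost_scheme(4, 3, 1), cost_scheme(3, 6, 1))
}

#' Import an externally produced per-family event table
#'
#' Reads a TSV in the `events_per_branch.tsv` schema (family, node or
#' node_name, gains_origination, gains_duplication, gains_transfer,
#' losses, vertical_passages, copies) so event tables produced by other
#' reconciliation tools can feed the downstream analytics.
#'
#' @param path TSV path.
#' @param species the `species_tree` the table refers to.
#' @return an `event_table` data.frame.
#' @export
read_event_table <- function(path, species) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "gains_origination", "gains_duplication",
            "gains_transfer", "losses", "vertical_passages", "copies")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$node)) {
    if (is.null(df$node_name)) stop("need a node or node_name column")
    df$node <- match(df$node_name, species$node_name)
  }
  if (anyNA(df$node) || any(df$node < 1 | df$node > species$n_nodes))
    stop("event table references unknown species branch", call. = FALSE)
  df$node_name <- species$node_name[df$node]
  structure(df, class = c("event_table", "data.frame"))
}
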