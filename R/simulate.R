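#' Configuration for the gene-family birth-and-death simulator
#'
#' Rates are per gene copy per unit branch length (the species tree's
#' substitutions/site scale is used directly as the simulation clock).
#'
#' @param dup_rate duplication rate (delta).
#' @param transfer_rate transfer rate (tau).
#' @param loss_rate loss rate (lambda).
#' @param origination `"root"` (every family originates at the species
#'   root), `"random"` (one origination branch per family, drawn with
#'   probability proportional to branch length), or a node id/name.
#' @param n_families number of families to simulate.
#' @param seed integer seed.
#' @param min_family_size families with fewer surviving genes are flagged
#'   as ineligible for reconciliation (default 4, the usual floor for a
#'   meaningful rooted binary gene tree).
#' @param length_weighted_transfer when TRUE (default) the transfer
#'   recipient branch is drawn among branches incomparable to the donor
#'   with probability proportional to branch length; when FALSE uniformly.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(dup_rate = 0.1, transfer_rate = 0.1, loss_rate = 0.1,
                       origination = "root", n_families = 100L, seed = 1L,
                       min_family_size = 4L, length_weighted_transfer = TRUE) {
  stopifnot(dup_rate >= 0, transfer_rate >= 0, loss_rate >= 0,
            n_families >= 1)
  structure(list(dup_rate = dup_rate, transfer_rate = transfer_rate,
                 loss_rate = loss_rate, origination = origination,
                 n_families = as.integer(n_families), seed = as.integer(seed),
                 min_family_size = as.integer(min_family_size),
                 length_weighted_transfer = isTRUE(length_weighted_transfer)),
            class = "sim_config")
}

# branches incomparable to each branch: neither ancestor nor descendant,
# and never the root (the root has no branch above it to land on)
incomparable_sets <- function(tree) {
  anc <- ancestor_matrix(tree)
  lapply(seq_len(tree$n_nodes), function(s) {
    ok <- !anc[s, ] & !anc[, s] & seq_len(tree$n_nodes) != s &
      seq_len(tree$n_nodes) != tree$root
    which(ok)
  })
}

#' Simulate one gene family along a species tree
#'
#' Gillespie-style per-copy simulation: along a branch each copy waits an
#' exponential time with total rate delta+tau+lambda; a duplication
#' splits the copy in place, a loss prunes it, and a transfer re-seeds
#' one copy at the top of a branch incomparable to the donor (the donor
#' copy continues), matching the undated DTL model's admissible
#' transfers. Copies reaching a speciation node continue into both child
#' branches; copies reaching leaves become gene-tree leaves.
#'
#' Uses the current R RNG state; callers control reproducibility with
#' `set.seed()` (or use [simulate_dataset()]).
#'
#' @param species a `species_tree`.
#' @param cfg a [sim_config()].
#' @param family family identifier used in gene labels (`fam<k>`).
#' @return list with `gene` (a `gene_tree`, or NULL if fewer than two
#'   copies survive), `newick` (character or NA), `events` (data.frame:
#'   family, kind, branch, recipient, lineage, new_lineage; kinds include
#'   `speciation` and `extant` bookkeeping rows so the log replays to the
#'   emitted tree), `copies` (true copy count at every species node),
#'   `n_leaves`, `eligible`.
#' @export
simulate_family <- function(species, cfg, family = "fam1") {
  stopifnot(inherits(species, "species_tree"), inherits(cfg, "sim_config"))
  inc <- incomparable_sets(species)
  bl <- species$branch_length
  rates <- c(dup = cfg$dup_rate, transfer = cfg$transfer_rate,
             loss = cfg$loss_rate)
  rtot <- sum(rates)

  copies <- numeric(species$n_nodes)
  ev <- list(kind = character(0), branch = integer(0), recipient = NA_integer_[0],
             lineage = integer(0), new_lineage = NA_integer_[0])
  n_ev <- 0L
  log_ev <- function(kind, branch, recipient = NA_integer_,
                     lineage = NA_integer_, new_lineage = NA_integer_) {
    n_ev <<- n_ev + 1L
    ev$kind[n_ev] <<- kind
    ev$branch[n_ev] <<- branch
    ev$recipient[n_ev] <<- recipient
    ev$lineage[n_ev] <<- lineage
    ev$new_lineage[n_ev] <<- new_lineage
  }

  lin_counter <- 0L
  new_lin <- function() { lin_counter <<- lin_counter + 1L; lin_counter }
  gene_counter <- 0L

  # returns a Newick fragment for the surviving subtree, or NULL if extinct
  sim_copy <- function(s, pos, lin) {
    repeat {
      remaining <- bl[s] - pos
      t <- if (rtot > 0) stats::rexp(1, rtot) else Inf
      if (t >= remaining) {
        copies[s] <<- copies[s] + 1
        if (is_leaf(species, s)) {
          gene_counter <<- gene_counter + 1L
          lab <- paste0(species$node_name[s], "|", family, "_g", gene_counter)
          log_ev("extant", s, lineage = lin)
          return(lab)
        }
        ch <- species$children[[s]]
        l2 <- new_lin()
        log_ev("speciation", s, lineage = lin, new_lineage = l2)
        left <- sim_copy(ch[1], 0, lin)
        right <- sim_copy(ch[2], 0, l2)
        return(join_frag(left, right))
      }
      pos <- pos + t
      kind <- sample(names(rates), 1, prob = rates / rtot)
      if (kind == "loss") {
        log_ev("loss", s, lineage = lin)
        return(NULL)
      }
      if (kind == "dup") {
        l2 <- new_lin()
        log_ev("duplication", s, lineage = lin, new_lineage = l2)
        left <- sim_copy_from(s, pos, lin)      # continuation, same lineage
        right <- sim_copy(s, pos, l2)
        return(join_frag(left, right))
      }
      # transfer
      cand <- inc[[s]]
      if (!length(cand)) next                  # no admissible recipient
      w <- if (cfg$length_weighted_transfer) bl[cand] else rep(1, length(cand))
      if (all(w == 0)) w <- rep(1, length(cand))
      r <- cand[sample.int(length(cand), 1, prob = w)]
      l2 <- new_lin()
      log_ev("transfer", s, recipient = r, lineage = lin, new_lineage = l2)
      left <- sim_copy_from(s, pos, lin)        # donor continues
      right <- sim_copy(r, 0, l2)
      return(join_frag(left, right))
    }
  }
  # indirection so the donor continuation is a plain recursive call
  sim_copy_from <- function(s, pos, lin) sim_copy(s, pos, lin)

  orig <- origination_branch(species, cfg)
  lin0 <- new_lin()
  log_ev("origination", orig, lineage = lin0)
  frag <- if (orig == species$root) {
    # copy appears at the root node itself
    copies[species$root] <- copies[species$root] + 1
    ch <- species$children[[species$root]]
    l2 <- new_lin()
    log_ev("speciation", species$root, lineage = lin0, new_lineage = l2)
    join_frag(sim_copy(ch[1], 0, lin0), sim_copy(ch[2], 0, l2))
  } else {
    sim_copy(orig, 0, lin0)
  }

  events <- data.frame(family = family, kind = ev$kind, branch = ev$branch,
                       recipient = ev$recipient, lineage = ev$lineage,
                       new_lineage = ev$new_lineage,
                       stringsAsFactors = FALSE)
  n_leaves <- sum(events$kind == "extant")
  gene <- NULL; nwk <- NA_character_
  if (!is.null(frag) && n_leaves >= 2) {
    nwk <- paste0(frag, ";")
    gene <- suppressWarnings(read_newick(nwk, kind = "gene"))
  }
  list(gene = gene, newick = nwk, events = events, copies = copies,
       n_leaves = n_leaves, eligible = n_leaves >= cfg$min_family_size,
       family = family)
}

join_frag <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  paste0("(", a, ",", b, ")")
}

origination_branch <- function(species, cfg) {
  o <- cfg$origination
  if (identical(o, "root")) return(species$root)
  if (identical(o, "random")) {
    cand <- setdiff(seq_len(species$n_nodes), species$root)
    w <- species$branch_length[cand]
    if (all(w == 0)) w <- rep(1, length(cand))
    return(cand[sample.int(length(cand), 1, prob = w)])
  }
  resolve_node(species, o)
}

#' Simulate a dataset of gene families
#'
#' Reproducible given `cfg$seed`. Returns the families, the aggregated
#' ground-truth event log, per-node true copy counts, and an orthogroup
#' membership table recoverable from the `<genome>|fam<k>_g<j>` leaf
#' labels alone.
#'
#' @param species a `species_tree`.
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset`: `families` (list of
#'   [simulate_family()] results), `truth` (row-bound event log),
#'   `copies` (matrix family x species node), `membership` (data.frame
#'   gene/family/genome), `eligible` (logical vector), `config`.
#' @export
simulate_dataset <- function(species, cfg) {
  set.seed(cfg$seed)
  fams <- vector("list", cfg$n_families)
  for (k in seq_len(cfg$n_families))
    fams[[k]] <- simulate_family(species, cfg, family = paste0("fam", k))
  truth <- do.call(rbind, lapply(fams, `[[`, "events"))
  copies <- do.call(rbind, lapply(fams, `[[`, "copies"))
  rownames(copies) <- vapply(fams, `[[`, "", "family")
  membership <- do.call(rbind, lapply(fams, function(f) {
    if (is.null(f$gene)) return(NULL)
    data.frame(gene = f$gene$phylo$tip.label, family = f$family,
               genome = f$gene$genome, stringsAsFactors = FALSE)
  }))
  structure(list(families = fams, truth = truth, copies = copies,
                 membership = membership,
                 eligible = vapply(fams, `[[`, TRUE, "eligible"),
                 config = cfg, species = species),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d families (%d eligible), %d true events\n",
              length(x$families), sum(x$eligible), nrow(x$truth)))
  invisible(x)
}

#' Rebuild a gene tree from a family's ground-truth event log
#'
#' Independent replay of the logged lineage genealogy: each
#' duplication/transfer/speciation row is a binary split of its lineage,
#' losses terminate lineages, `extant` rows are leaves. Used to assert
#' the log/tree consistency invariant.
#'
#' @param events the `events` data.frame of one family.
#' @return a Newick string, or NA if fewer than two copies survive.
#' @export
replay_truth <- function(events) {
  split_kinds <- c("duplication", "transfer", "speciation")
  by_lin <- split(seq_len(nrow(events)), events$lineage)
  build <- function(lin) {
    rows <- by_lin[[as.character(lin)]]
    rows <- rows[events$kind[rows] != "origination"]
    frag <- NULL
    # process this lineage's rows chronologically (log order)
    build_from <- function(i) {
      if (i > length(rows)) return(NULL)
      r <- rows[i]
      k <- events$kind[r]
      if (k == "loss") return(NULL)
      if (k == "extant") {
        lab <- paste0("L", r)   # positional label; topology-only replay
        return(lab)
      }
      if (k %in% split_kinds) {
        left <- build_from(i + 1)
        right <- build(events$new_lineage[r])
        return(join_frag(left, right))
      }
      build_from(i + 1)
    }
    build_from(1)
  }
  root_lin <- events$lineage[events$kind == "origination"][1]
  frag <- build(root_lin)
  if (is.null(frag) || !grepl(",", frag)) return(NA_character_)
  paste0(frag, ";")
}

#' Write a simulated dataset to disk
#'
#' Emits one Newick per family under `<dir>/gene_trees/`, plus
#' `truth_events.tsv` and `og_membership.tsv`.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "gene_trees"), recursive = TRUE,
             showWarnings = FALSE)
  for (f in dataset$families) {
    if (!is.na(f$newick))
      writeLines(f$newick, file.path(dir, "gene_trees",
                                     paste0(f$family, ".nwk")))
  }
  truth <- dataset$truth
  truth$branch_name <- dataset$species$node_name[truth$branch]
  utils::write.table(truth, file.path(dir, "truth_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$membership, file.path(dir, "og_membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' True per-branch event table from a simulation
#'
#' Collapses a dataset's ground-truth log into the same per-branch
#' accounting produced by reconciliation ([build_event_table()]):
#' per family and species branch, gains by mechanism, losses, vertical
#' passages (copies crossing an internal node) and copy counts.
#'
#' @param dataset a `sim_dataset`.
#' @return data.frame in `event_table` layout.
#' @export
truth_event_table <- function(dataset) {
  sp <- dataset$species
  out <- lapply(dataset$families, function(f) {
    ev <- f$events
    tab <- function(kind, col = "branch")
      tabulate(ev[[col]][ev$kind == kind], nbins = sp$n_nodes)
    gains_o <- tabulate(ev$branch[ev$kind == "origination"], nbins = sp$n_nodes)
    gains_d <- tab("duplication")
    gains_t <- tabulate(ev$recipient[ev$kind == "transfer"], nbins = sp$n_nodes)
    losses <- tab("loss")
    copies <- f$copies
    vert <- ifelse(seq_len(sp$n_nodes) > sp$n_tips, copies, 0)
    data.frame(family = f$family, node = seq_len(sp$n_nodes),
               node_name = sp$node_name,
               gains_origination = gains_o, gains_duplication = gains_d,
               gains_transfer = gains_t, losses = losses,
               vertical_passages = vert, copies = copies,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("event_table", "data.frame"))
}
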