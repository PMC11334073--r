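#' Build the per-family, per-branch event table
#'
#' Stacks the across-trial median accounting of each reconciled family
#' into one table: per species branch, gains by mechanism (origination,
#' duplication, transfer), losses, vertical passages (gene lineages
#' crossing the speciation node at the bottom of the branch), and the
#' expected gene-copy count on the branch. Values can be fractional
#' (trial medians); sums across families are taken on the raw values and
#' rounded only after summation.
#'
#' @param trials list of `dtl_trials` (from [reconcile_dataset()]), or an
#'   already-stacked data.frame in the same layout (e.g. from
#'   [read_event_table()] or [truth_event_table()]).
#' @param species the common `species_tree`.
#' @return an `event_table` data.frame.
#' @export
build_event_table <- function(trials, species) {
  if (is.data.frame(trials)) {
    df <- trials
  } else {
    df <- do.call(rbind, lapply(trials, `[[`, "per_branch"))
  }
  if (any(df$node < 1 | df$node > species$n_nodes))
    stop("event table references unknown species branch", call. = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("event_table", "data.frame"))
}

et_gains <- function(table)
  table$gains_origination + table$gains_duplication + table$gains_transfer

#' Ancestral (and extant) gene counts per species node
#'
#' Gene count at a node is the rounded sum over families of copy numbers
#' on the node's branch: a conservative lower bound on the true ancestral
#' repertoire, since only families observed in the data can contribute.
#' `mode = "presence"` counts families with at least one copy instead.
#'
#' @param table an `event_table`.
#' @param mode `"copies"` (default) or `"presence"`.
#' @return data.frame `node`, `node_name`, `count`.
#' @export
ancestral_gene_counts <- function(table, mode = c("copies", "presence")) {
  mode <- match.arg(mode)
  val <- if (mode == "copies") table$copies else as.numeric(table$copies > 0)
  agg <- stats::aggregate(val, by = list(node = table$node), FUN = sum)
  nm <- table$node_name[match(agg$node, table$node)]
  data.frame(node = agg$node, node_name = nm, count = round(agg$x))
}

# a branch belongs to a clade iff all its descendant leaves do (stem
# branches included); mixed branches fall into the `deep` bucket
branch_clades <- function(species, clades, deep = "deep") {
  if (!all(species$node_name[seq_len(species$n_tips)] %in% names(clades)))
    stop("clade partition must cover every species leaf", call. = FALSE)
  tb <- tips_below(species)
  vapply(seq_len(species$n_nodes), function(v) {
    cl <- unique(clades[species$node_name[tb[[v]]]])
    if (length(cl) == 1) cl else deep
  }, "")
}

#' Gain-mechanism breakdown per clade
#'
#' Splits gene gains attributed to the branches of each clade into the
#' three mechanisms (origination, duplication, transfer/vHGT) and reports
#' percentages of the clade's total gains. Optionally restricts to a
#' family subset (e.g. viral-specific orthogroups).
#'
#' @param table an `event_table`.
#' @param species the `species_tree`.
#' @param clades named character vector, leaf name -> clade label.
#' @param family_labels optional data.frame (family, label) as produced by
#'   [classify_viral_specific()].
#' @param subset `"all"`, `"viral_specific"` or `"nonviral_specific"`.
#' @return data.frame: clade, total gains, percent per mechanism.
#'   Clades whose branches carry no gains are absent from the output.
#' @export
gain_mechanism_breakdown <- function(table, species, clades,
                                     family_labels = NULL,
                                     subset = c("all", "viral_specific",
                                                "nonviral_specific")) {
  subset <- match.arg(subset)
  if (subset != "all") {
    if (is.null(family_labels))
      stop("family_labels required for subset = ", subset, call. = FALSE)
    keep <- family_labels$family[family_labels$label == subset]
    table <- table[table$family %in% keep, , drop = FALSE]
  }
  bc <- branch_clades(species, clades)
  cl <- bc[table$node]
  agg <- function(v) tapply(v, cl, sum)
  o <- agg(table$gains_origination); d <- agg(table$gains_duplication)
  t <- agg(table$gains_transfer)
  tot <- o + d + t
  keep <- !is.na(tot) & tot > 0
  data.frame(clade = names(tot)[keep], total_gains = as.numeric(tot[keep]),
             pct_origination = 100 * as.numeric(o[keep] / tot[keep]),
             pct_duplication = 100 * as.numeric(d[keep] / tot[keep]),
             pct_vhgt = 100 * as.numeric(t[keep] / tot[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Root-to-leaf gain/loss trajectory
#'
#' Sums event counts over all branches on the path from the root to a
#' leaf. Per family the replay identity
#' `copies(root) + gains - losses = copies(leaf)` holds along the path.
#'
#' @param table an `event_table`.
#' @param species the `species_tree`.
#' @param leaf leaf id or name.
#' @return list: `leaf`, `genes_at_leaf`, `gains`, `losses`,
#'   `per_family` data.frame.
#' @export
per_leaf_trajectory <- function(table, species, leaf) {
  leaf <- resolve_node(species, leaf)
  if (!is_leaf(species, leaf)) stop("not a leaf: ", leaf, call. = FALSE)
  path <- ancestor_chain(species, leaf)     # leaf .. root, all branches
  sub <- table[table$node %in% path, , drop = FALSE]
  pf <- do.call(rbind, lapply(split(sub, sub$family), function(x) {
    data.frame(family = x$family[1],
               gains = sum(et_gains(x)), losses = sum(x$losses),
               leaf_copies = sum(x$copies[x$node == leaf]),
               root_copies = sum(x$copies[x$node == species$root]))
  }))
  rownames(pf) <- NULL
  list(leaf = species$node_name[leaf],
       genes_at_leaf = sum(pf$leaf_copies),
       gains = sum(pf$gains), losses = sum(pf$losses),
       per_family = pf)
}

#' Percentage shares of gains and losses (and other two-part totals)
#'
#' Given total gain and loss event counts, returns the percentage each
#' contributes to all events, e.g. `event_shares(17826, 15785)` gives
#' 53.04% gains and 46.96% losses.
#'
#' @param gains,losses non-negative totals.
#' @return named numeric vector `gain_pct`, `loss_pct`.
#' @export
event_shares <- function(gains, losses) {
  stopifnot(gains >= 0, losses >= 0, gains + losses > 0)
  c(gain_pct = 100 * gains / (gains + losses),
    loss_pct = 100 * losses / (gains + losses))
}

#' Write an event table as TSV
#' @param table an `event_table`.
#' @param file output path.
#' @export
write_event_table <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
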