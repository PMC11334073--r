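#' Mann-Whitney U test with Cliff's delta
#'
#' The U statistic counts pairs with `x > y` plus half the ties. The
#' two-sided p-value uses exact enumeration of all group assignments when
#' both groups have at most `exact_max` observations (ties handled via
#' midranks), and the tie-corrected normal approximation (no continuity
#' correction) otherwise. Cliff's delta is the probability-of-superiority
#' difference `(#(x>y) - #(x<y)) / (n_x n_y)` and satisfies
#' `delta = 2U/(n_x n_y) - 1`.
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   default `NULL` chooses it when both groups are small.
#' @param exact_max group-size ceiling for automatic exact enumeration.
#' @return list: `U`, `p_value`, `delta`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_max = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0)
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  delta <- 2 * U / (nx * ny) - 1
  if (is.null(exact)) exact <- nx <= exact_max && ny <= exact_max
  if (exact) {
    combs <- utils::combn(nx + ny, nx)
    usum <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    u_hi <- max(U, nx * ny - U); u_lo <- min(U, nx * ny - U)
    tol <- 1e-9
    p <- (sum(usum >= u_hi - tol) + sum(usum <= u_lo + tol)) / ncol(combs)
    p <- min(1, p)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) { p <- 1 }
    else {
      z <- (U - nx * ny / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p_value = p, delta = delta, method = method)
}

#' @rdname mann_whitney_u
#' @export
cliffs_delta <- function(x, y) {
  gt <- sum(outer(x, y, ">")); lt <- sum(outer(x, y, "<"))
  (gt - lt) / (length(x) * length(y))
}

# -- lineage attribution -----------------------------------------------------

#' Attribute species branches to lineages
#'
#' A branch belongs to a lineage iff all its descendant leaves do (stem
#' branches included); branches whose descendants span several lineages
#' go to the `deep` pseudo-lineage.
#'
#' @param species a `species_tree`.
#' @param lineages named character vector: leaf name -> lineage.
#' @param deep label for the mixed/deep bucket.
#' @return character vector over species node ids.
#' @export
branch_lineages <- function(species, lineages, deep = "deep") {
  branch_clades(species, lineages, deep = deep)
}

#' Cut a species tree into k monophyletic lineages
#'
#' Convenience for synthetic data: repeatedly splits the clade with the
#' most leaves until `k` groups exist, then labels leaves `lin1..link`.
#'
#' @param species a `species_tree`.
#' @param k number of lineages.
#' @return named character vector leaf name -> lineage.
#' @export
assign_lineages <- function(species, k = 4L) {
  stopifnot(k >= 1, k <= species$n_tips)
  tb <- tips_below(species)
  groups <- list(species$root)
  repeat {
    sizes <- vapply(groups, function(v) length(tb[[v]]), 0L)
    if (length(groups) >= k) break
    i <- which.max(sizes)
    v <- groups[[i]]
    if (is_leaf(species, v)) break
    groups <- c(groups[-i], as.list(species$children[[v]]))
  }
  out <- character(0)
  for (i in seq_along(groups)) {
    nm <- species$node_name[tb[[groups[[i]]]]]
    out[nm] <- paste0("lin", i)
  }
  out[species$node_name[seq_len(species$n_tips)]]
}

# -- vHGT matrix -------------------------------------------------------------

#' Donor-recipient vHGT frequency matrix between lineages
#'
#' Sums inferred transfer counts between lineages ignoring direction
#' (diagonal = intra-lineage), normalizes to frequencies
#' `F = No_vHGT / (N_lineage1 * N_lineage2)` using lineage sizes (leaf
#' counts), and min-max rescales the frequencies to `[0, 1]`.
#'
#' @param transfers data.frame with `donor`, `recipient` (species node
#'   ids) and a count column (`median_count` preferred, else `count`);
#'   e.g. row-bound `transfer_pairs` from [reconcile_dataset()].
#' @param species the `species_tree`.
#' @param lineages named character vector leaf -> lineage.
#' @param deep_size size assigned to the `deep` pseudo-lineage (defaults
#'   to the total leaf count).
#' @return object of class `vhgt_matrix`: `raw`, `sizes`, `freq`,
#'   `scaled` (all lineage x lineage, symmetric).
#' @export
vhgt_matrix <- function(transfers, species, lineages, deep_size = NULL) {
  bl <- branch_lineages(species, lineages)
  lins <- sort(unique(lineages))
  sizes <- table(factor(lineages, levels = lins))
  if (any(sizes == 0))
    stop("lineage of size 0: ", names(sizes)[sizes == 0][1], call. = FALSE)
  cnt <- transfer_count_col(transfers)
  used_deep <- nrow(transfers) > 0 &&
    any(bl[transfers$donor] == "deep" | bl[transfers$recipient] == "deep")
  if (any(bl == "deep") && used_deep) {
    lins <- c(lins, "deep")
    sizes <- c(sizes, deep = if (is.null(deep_size)) species$n_tips
                             else deep_size)
    names(sizes)[length(sizes)] <- "deep"
  }
  raw <- matrix(0, length(lins), length(lins), dimnames = list(lins, lins))
  if (nrow(transfers)) {
    li <- bl[transfers$donor]; lj <- bl[transfers$recipient]
    for (k in seq_len(nrow(transfers))) {
      raw[li[k], lj[k]] <- raw[li[k], lj[k]] + cnt[k]
      if (li[k] != lj[k]) raw[lj[k], li[k]] <- raw[lj[k], li[k]] + cnt[k]
    }
  }
  nv <- as.numeric(sizes[lins])
  freq <- raw / outer(nv, nv)
  rng <- range(freq)
  scaled <- if (diff(rng) > 0) (freq - rng[1]) / diff(rng)
            else freq * 0
  structure(list(raw = raw, sizes = sizes, freq = freq, scaled = scaled,
                 lineages = lins),
            class = "vhgt_matrix")
}

transfer_count_col <- function(transfers) {
  if (!is.null(transfers$median_count)) return(transfers$median_count)
  if (!is.null(transfers$count)) return(transfers$count)
  rep(1, nrow(transfers))
}

#' @export
print.vhgt_matrix <- function(x, ...) {
  cat("<vhgt_matrix> lineages:", paste(x$lineages, collapse = ", "), "\n")
  print(round(x$freq, 4))
  invisible(x)
}

# -- distance profile --------------------------------------------------------

#' All unordered incomparable branch pairs with distances
#'
#' The admissible donor-recipient pairs of the undated transfer model
#' (neither branch ancestral to the other; root excluded), with their
#' node-to-node patristic distances and branch-length product weights.
#'
#' @param species a `species_tree`.
#' @return data.frame `a`, `b`, `distance`, `w`.
#' @export
admissible_branch_pairs <- function(species) {
  anc <- ancestor_matrix(species)
  dmat <- node_distance_matrix(species)
  n <- species$n_nodes
  keep <- which(upper.tri(matrix(TRUE, n, n)) & !anc & !t(anc),
                arr.ind = TRUE)
  keep <- keep[keep[, 1] != species$root & keep[, 2] != species$root, ,
               drop = FALSE]
  data.frame(a = keep[, 1], b = keep[, 2],
             distance = dmat[keep],
             w = species$branch_length[keep[, 1]] *
               species$branch_length[keep[, 2]])
}

#' Mean vHGT count by donor-recipient distance bin
#'
#' Bins the node-to-node patristic distance between transfer donors and
#' recipients and reports, per bin, the mean transfer count over all
#' admissible (incomparable) branch pairs in the bin -- pairs with no
#' inferred transfer contribute zero, so the profile is the average
#' number of transfers per pair at that distance. Fractional per-pair
#' counts (trial medians) are allowed.
#'
#' @param transfers data.frame with `donor`, `recipient`, count column.
#' @param species the `species_tree`.
#' @param bins number of equal-width bins, or a vector of break points.
#' @return data.frame `bin_lo`, `bin_hi`, `n_pairs`, `total_count`,
#'   `mean_count` (NA where a bin holds no admissible pair).
#' @export
distance_profile <- function(transfers, species, bins = 10L) {
  pairs <- admissible_branch_pairs(species)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = ":")
  pairs$count <- 0
  if (nrow(transfers)) {
    cnt <- transfer_count_col(transfers)
    agg <- tapply(cnt, key(transfers$donor, transfers$recipient), sum)
    i <- match(key(pairs$a, pairs$b), names(agg))
    pairs$count[!is.na(i)] <- agg[i[!is.na(i)]]
  }
  if (length(bins) == 1L)
    bins <- seq(0, max(pairs$distance) * (1 + 1e-9), length.out = bins + 1)
  cut_i <- cut(pairs$distance, breaks = bins, include.lowest = TRUE)
  tot <- tapply(pairs$count, cut_i, sum)
  npair <- tapply(pairs$count, cut_i, length)
  data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1],
             n_pairs = ifelse(is.na(npair), 0L, npair),
             total_count = ifelse(is.na(tot), 0, tot),
             mean_count = as.numeric(tot) / as.numeric(npair))
}

# -- host overlap ------------------------------------------------------------

#' Host-range overlap test for inter-lineage vHGT frequencies
#'
#' Splits the inter-lineage cells of a [vhgt_matrix()] into lineage pairs
#' whose host-phylum sets intersect versus those that do not, and
#' compares the vHGT frequencies with a Mann-Whitney U test plus Cliff's
#' delta.
#'
#' @param vm a `vhgt_matrix`.
#' @param hosts data.frame `lineage`, `host_phylum` (one row per lineage
#'   x host phylum).
#' @param use `"freq"` (default) or `"raw"` values.
#' @return list: `U`, `p_value`, `delta`, `n_overlap`, `n_disjoint`,
#'   `method`.
#' @export
host_overlap_test <- function(vm, hosts, use = c("freq", "raw")) {
  use <- match.arg(use)
  stopifnot(inherits(vm, "vhgt_matrix"))
  hs <- split(hosts$host_phylum, hosts$lineage)
  if (any(lengths(hs) == 0)) stop("empty host set", call. = FALSE)
  lins <- setdiff(vm$lineages, "deep")
  lins <- intersect(lins, names(hs))
  if (length(lins) < 2)
    stop("need at least two host-annotated lineages", call. = FALSE)
  vals_o <- numeric(0); vals_d <- numeric(0)
  m <- vm[[use]]
  for (i in seq_along(lins)) for (j in seq_len(i - 1)) {
    v <- m[lins[i], lins[j]]
    if (length(intersect(hs[[lins[i]]], hs[[lins[j]]])) > 0)
      vals_o <- c(vals_o, v) else vals_d <- c(vals_d, v)
  }
  if (length(vals_o) == 0 || length(vals_d) == 0)
    stop("one host-overlap group is empty: need lineage pairs both with ",
         "and without overlapping host types", call. = FALSE)
  res <- mann_whitney_u(vals_o, vals_d)
  c(res, list(n_overlap = length(vals_o), n_disjoint = length(vals_d)))
}

# -- propensities ------------------------------------------------------------

#' Per-family vHGT propensities
#'
#' For each family with detected transfers, computes the propensity of
#' vHGT relative to vertical transmission,
#' `P^VT = f_vHGT / (f_vHGT + f_VT)`, and relative to duplication,
#' `P^D = f_vHGT / (f_vHGT + f_D)`, where the `f` values are across-trial
#' mean counts of transfers, vertical passages, and duplications. A value
#' of 0.5 means the two mechanisms occur equally often; duplication-free
#' families saturate at `P^D = 1`. Families whose median transfer count
#' is zero are excluded (no detected vHGT). When functional categories
#' are supplied, group medians are compared with a Kruskal-Wallis test.
#'
#' @param trials list of `dtl_trials`, or a data.frame with columns
#'   `family`, `f_vhgt`, `f_vt`, `f_d`, `detected`.
#' @param categories optional named vector family -> functional category.
#' @return list of class `propensity_set`: `records` (data.frame),
#'   `summary` (median/mean/sd of both propensities), `kruskal`
#'   (htest or NULL), `n_detected`, `n_total`.
#' @export
propensities <- function(trials, categories = NULL) {
  if (is.data.frame(trials)) {
    rec <- trials
  } else {
    rec <- do.call(rbind, lapply(trials, function(tr) {
      data.frame(family = tr$family,
                 f_vhgt = tr$totals["mean", "transfer"],
                 f_vt = tr$totals["mean", "vertical_passages"],
                 f_d = tr$totals["mean", "duplication"],
                 detected = tr$totals["median", "transfer"] > 0,
                 stringsAsFactors = FALSE)
    }))
  }
  n_total <- nrow(rec)
  rec <- rec[rec$detected & (rec$f_vhgt + rec$f_vt) > 0, , drop = FALSE]
  if (nrow(rec) == 0)
    stop("no families with detected vHGT", call. = FALSE)
  rec$P_vt <- rec$f_vhgt / (rec$f_vhgt + rec$f_vt)
  rec$P_d <- ifelse(rec$f_vhgt + rec$f_d > 0,
                    rec$f_vhgt / (rec$f_vhgt + rec$f_d), NA)
  if (!is.null(categories)) rec$category <- categories[rec$family]
  kw <- NULL
  if (!is.null(categories) && length(unique(stats::na.omit(rec$category))) > 1)
    kw <- stats::kruskal.test(rec$P_vt, factor(rec$category))
  summ <- rbind(
    P_vt = c(median = stats::median(rec$P_vt), mean = mean(rec$P_vt),
             sd = stats::sd(rec$P_vt)),
    P_d = c(median = stats::median(rec$P_d, na.rm = TRUE),
            mean = mean(rec$P_d, na.rm = TRUE),
            sd = stats::sd(rec$P_d, na.rm = TRUE)))
  structure(list(records = rec, summary = summ, kruskal = kw,
                 n_detected = nrow(rec), n_total = n_total),
            class = "propensity_set")
}

#' @export
print.propensity_set <- function(x, ...) {
  cat(sprintf("<propensity_set> %d/%d families with detected vHGT\n",
              x$n_detected, x$n_total))
  print(round(x$summary, 4))
  invisible(x)
}

# -- RED-normalized rates ----------------------------------------------------

#' Event rates along relative evolutionary divergence
#'
#' Sums event counts per species branch across families, converts them to
#' rates `ln(n_events + 1) / branch_length`, attaches each node's RED
#' value, and compares the recent epoch (RED >= `threshold`) against the
#' earlier one per event kind with a Mann-Whitney U test. Branches of
#' zero length (and the root, which has no branch) are excluded with a
#' warning when they carry events.
#'
#' @param table an `event_table`.
#' @param red data.frame from [compute_red()].
#' @param species the `species_tree`.
#' @param threshold RED split point for the recent epoch (default 0.95).
#' @return list of class `rate_curves`: `rates` (data.frame node, red,
#'   branch_length, kind, n_events, rate, recent), `tests` (per-kind U,
#'   p, delta), `excluded` (node ids dropped).
#' @export
rate_curves <- function(table, red, species, threshold = 0.95) {
  kinds <- c(origination = "gains_origination",
             duplication = "gains_duplication",
             transfer = "gains_transfer", loss = "losses")
  sums <- lapply(kinds, function(cl)
    tapply(table[[cl]], table$node, sum))
  nodes <- as.integer(names(sums[[1]]))
  bl <- species$branch_length[nodes]
  drop <- nodes == species$root | bl <= 0
  carrying <- Reduce(`|`, lapply(sums, function(s) s > 0))
  noisy <- drop & carrying & nodes != species$root
  if (any(noisy))
    warning("excluding ", sum(noisy),
            " zero-length branches carrying events from rate analysis")
  redv <- red$red[match(nodes, red$node)]
  rows <- lapply(names(kinds), function(k) {
    n_ev <- as.numeric(sums[[k]])
    data.frame(node = nodes, node_name = species$node_name[nodes],
               red = redv, branch_length = bl, kind = k, n_events = n_ev,
               stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, rows)
  rates <- rates[!(rates$node %in% nodes[drop]), , drop = FALSE]
  rates$rate <- log1p(rates$n_events) / rates$branch_length
  rates$recent <- rates$red >= threshold
  tests <- do.call(rbind, lapply(names(kinds), function(k) {
    sub <- rates[rates$kind == k, ]
    if (!any(sub$recent) || all(sub$recent))
      return(data.frame(kind = k, U = NA, p_value = NA, delta = NA))
    mw <- mann_whitney_u(sub$rate[sub$recent], sub$rate[!sub$recent])
    data.frame(kind = k, U = mw$U, p_value = mw$p_value, delta = mw$delta)
  }))
  structure(list(rates = rates, tests = tests,
                 excluded = nodes[drop], threshold = threshold),
            class = "rate_curves")
}

#' @export
print.rate_curves <- function(x, ...) {
  cat(sprintf("<rate_curves> epoch split at RED >= %g\n", x$threshold))
  print(x$tests)
  invisible(x)
}
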