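test_that("Mann-Whitney exact enumeration matches hand counts", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$delta, -1)
  expect_equal(res$p_value, 0.1)   # 2 of the 20 assignments are as extreme
  res2 <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res2$delta, 1)
  expect_equal(res2$p_value, 0.1)
  # identical groups: delta 0, p 1
  res3 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res3$delta, 0)
  expect_equal(res3$p_value, 1)
})

test_that("exact Mann-Whitney agrees with wilcox.test without ties", {
  set.seed(5)
  for (i in 1:30) {
    x <- stats::rnorm(sample(3:8, 1)); y <- stats::rnorm(sample(3:8, 1))
    mine <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("tie-corrected normal approximation matches the reference to 1e-9", {
  set.seed(9)
  for (i in 1:100) {
    x <- sample(0:6, sample(9:25, 1), replace = TRUE)
    y <- sample(0:6, sample(9:25, 1), replace = TRUE)
    mine <- mann_whitney_u(x, y)
    expect_equal(mine$method, "normal approximation (tie-corrected)")
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Cliff's delta satisfies the 2U/(nm) - 1 identity", {
  set.seed(13)
  for (i in 1:50) {
    x <- sample(0:9, sample(2:12, 1), replace = TRUE)
    y <- sample(0:9, sample(2:12, 1), replace = TRUE)
    res <- mann_whitney_u(x, y)
    expect_equal(res$delta, 2 * res$U / (length(x) * length(y)) - 1,
                 tolerance = 1e-12)
    expect_equal(cliffs_delta(x, y), res$delta, tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("the vHGT matrix applies the size normalization and scaling", {
  # 30 leaves, lineages of size 10 and 20
  set.seed(2)
  phy <- ape::rtree(30, tip.label = paste0("G", 1:30))
  phy$edge.length <- rep(1, nrow(phy$edge))
  sp <- as_dtl_tree(phy, "species")
  lin <- stats::setNames(c(rep("lin1", 10), rep("lin2", 20)),
                         paste0("G", 1:30))
  # leaf branches G1 (lin1) and G30 (lin2): 4 transfers between lineages
  transfers <- data.frame(donor = rep(resolve_node(sp, "G1"), 4),
                          recipient = rep(resolve_node(sp, "G30"), 4),
                          median_count = 1)
  vm <- vhgt_matrix(transfers, sp, lin)
  expect_equal(vm$raw["lin1", "lin2"], 4)
  expect_equal(vm$freq["lin1", "lin2"], 4 / (10 * 20))
  expect_equal(vm$freq["lin2", "lin1"], vm$freq["lin1", "lin2"])
  # single nonzero cell: scaled 1, everything else 0
  expect_equal(vm$scaled["lin1", "lin2"], 1)
  expect_equal(sum(vm$scaled), 2)  # symmetric cell counted twice
  expect_true(all(vm$scaled >= 0 & vm$scaled <= 1))
})

test_that("a transfer-free simulation gives an all-zero vHGT matrix", {
  sp <- coal_species(12, seed = 3)
  ds <- simulate_dataset(sp, sim_config(transfer_rate = 0, n_families = 20,
                                        seed = 5))
  trials <- reconcile_dataset(ds, sp, n_trials = 3, seed = 7)
  transfers <- do.call(rbind, lapply(trials, `[[`, "transfer_pairs"))
  vm <- vhgt_matrix(transfers, sp, assign_lineages(sp, 3))
  expect_true(all(vm$raw == 0))
  expect_true(all(vm$scaled == 0))
})

test_that("the vHGT matrix stays symmetric and scaled on random runs", {
  sp <- coal_species(14, seed = 11)
  ds <- simulate_dataset(sp, sim_config(transfer_rate = 0.3, n_families = 30,
                                        seed = 13))
  trials <- reconcile_dataset(ds, sp, n_trials = 3, seed = 17)
  transfers <- do.call(rbind, lapply(trials, `[[`, "transfer_pairs"))
  vm <- vhgt_matrix(transfers, sp, assign_lineages(sp, 4))
  expect_equal(vm$freq, t(vm$freq))
  expect_true(all(vm$scaled >= 0 & vm$scaled <= 1))
  expect_equal(min(vm$scaled), 0)
  expect_equal(max(vm$scaled), 1)
})

test_that("distance profile localizes sister-leaf transfers to one bin", {
  sp <- abc_species()
  a <- resolve_node(sp, "A"); b <- resolve_node(sp, "B")
  transfers <- data.frame(donor = rep(a, 5), recipient = rep(b, 5),
                          median_count = 1)
  prof <- distance_profile(transfers, sp, bins = 5)
  expect_equal(sum(prof$total_count > 0), 1)
  occupied <- which(prof$total_count > 0)
  expect_true(prof$bin_lo[occupied] <= 2 && prof$bin_hi[occupied] >= 2)
  # zero transfers: profile exists but is empty
  prof0 <- distance_profile(transfers[0, ], sp, bins = 5)
  expect_true(all(prof0$total_count == 0))
})

test_that("simulated transfer distances follow the admissible-pair law", {
  # with rare transfers the donor is uniform over branch length and the
  # recipient length-weighted among incomparable branches; bin the
  # single-transfer families against that distribution
  sp <- coal_species(16, seed = 19)
  cfg <- sim_config(dup_rate = 0, transfer_rate = 0.02, loss_rate = 0,
                    n_families = 4000, seed = 23)
  ds <- simulate_dataset(sp, cfg)
  tr <- ds$truth[ds$truth$kind == "transfer", ]
  singles <- names(which(table(tr$family) == 1))
  tr <- tr[tr$family %in% singles, ]
  expect_gt(nrow(tr), 150)
  dm <- ape::dist.nodes(sp$phylo)
  obs_d <- dm[cbind(tr$branch, tr$recipient)]

  # expected ordered-pair probabilities
  anc <- ancestor_matrix(sp)
  bl <- sp$branch_length
  nodes <- setdiff(seq_len(sp$n_nodes), sp$root)
  probs <- c(); dists <- c()
  L <- sum(bl[nodes])
  for (i in nodes) {
    inc <- which(!anc[i, ] & !anc[, i] & seq_len(sp$n_nodes) != i &
                   seq_len(sp$n_nodes) != sp$root)
    wi <- sum(bl[inc])
    for (j in inc) {
      probs <- c(probs, (bl[i] / L) * (bl[j] / wi))
      dists <- c(dists, dm[i, j])
    }
  }
  qs <- stats::quantile(rep(dists, times = round(probs * 1e5)),
                        probs = c(0.25, 0.5, 0.75))
  breaks <- c(-Inf, qs, Inf)
  expected <- tapply(probs, cut(dists, breaks), sum)
  observed <- table(cut(obs_d, breaks))
  gof <- stats::chisq.test(as.numeric(observed), p = as.numeric(expected),
                           rescale.p = TRUE)
  expect_gt(gof$p.value, 0.01)
})

test_that("host overlap testing compares the right inter-lineage cells", {
  sp <- coal_species(16, seed = 29)
  lin <- assign_lineages(sp, 4)
  # transfers concentrated between lin pairs that will share hosts
  leaves <- split(names(lin), lin)
  leaf_id <- function(nm) resolve_node(sp, nm)
  transfers <- data.frame(
    donor = c(rep(leaf_id(leaves$lin1[1]), 6), leaf_id(leaves$lin3[1])),
    recipient = c(rep(leaf_id(leaves$lin2[1]), 6), leaf_id(leaves$lin4[1])),
    median_count = 1)
  vm <- vhgt_matrix(transfers, sp, lin)
  hosts <- data.frame(lineage = c("lin1", "lin2", "lin3", "lin4"),
                      host_phylum = c("Amoebozoa", "Amoebozoa",
                                      "Chlorophyta", "Haptophyta"))
  res <- host_overlap_test(vm, hosts)
  expect_equal(res$n_overlap + res$n_disjoint, 6)   # 4 choose 2 pairs
  expect_equal(res$n_overlap, 1)                    # only lin1-lin2 overlap
  expect_true(res$delta > 0)                        # overlap cell is largest
  # empty group is rejected
  hosts_all <- hosts; hosts_all$host_phylum <- "Amoebozoa"
  expect_error(host_overlap_test(vm, hosts_all), "empty")
})

test_that("propensity formulas and exclusions follow their definitions", {
  rec <- data.frame(family = c("f1", "f2", "f3"),
                    f_vhgt = c(2, 3, 0), f_vt = c(18, 0, 10),
                    f_d = c(1, 0, 2), detected = c(TRUE, TRUE, FALSE))
  pr <- propensities(rec)
  expect_equal(pr$n_detected, 2)
  expect_equal(pr$records$P_vt[pr$records$family == "f1"], 0.1)
  expect_equal(pr$records$P_d[pr$records$family == "f2"], 1)  # no dups
  expect_true(all(pr$records$P_vt >= 0 & pr$records$P_vt <= 1))

  # scale invariance: multiplying all frequencies leaves P unchanged
  rec2 <- rec; rec2[, c("f_vhgt", "f_vt", "f_d")] <-
    rec[, c("f_vhgt", "f_vt", "f_d")] * 7
  pr2 <- propensities(rec2)
  expect_equal(pr2$records$P_vt, pr$records$P_vt)
  expect_equal(pr2$records$P_d, pr$records$P_d)

  # P = 0.5 iff the two frequencies are equal
  rec3 <- data.frame(family = "f", f_vhgt = 4, f_vt = 4, f_d = 4,
                     detected = TRUE)
  pr3 <- propensities(rec3)
  expect_equal(pr3$records$P_vt, 0.5)
  expect_equal(pr3$records$P_d, 0.5)

  expect_error(propensities(rec[3, , drop = FALSE]), "no families")
})

test_that("Kruskal-Wallis on identical groups is null", {
  rec <- data.frame(family = paste0("f", 1:9),
                    f_vhgt = rep(c(1, 2, 3), 3),
                    f_vt = rep(c(9, 8, 7), 3), f_d = 1, detected = TRUE)
  cats <- stats::setNames(rep(c("K", "L", "V"), each = 3), rec$family)
  pr <- propensities(rec, categories = cats)
  expect_lt(unname(pr$kruskal$statistic), 1e-9)
  expect_gt(pr$kruskal$p.value, 0.999)
})

test_that("event rates follow ln(n+1)/branch-length", {
  sp <- abc_species()
  red <- compute_red(sp)
  tab <- data.frame(family = "f1", node = 1:5, node_name = sp$node_name,
                    gains_origination = 0, gains_duplication = 0,
                    gains_transfer = c(3, 0, 0, 0, 0),
                    losses = 0, vertical_passages = 0, copies = 1)
  sp$branch_length[1] <- 0.5
  rc <- rate_curves(build_event_table(tab, sp), red, sp)
  tr_rates <- rc$rates[rc$rates$kind == "transfer", ]
  expect_equal(tr_rates$rate[tr_rates$node == 1], log(4) / 0.5,
               tolerance = 1e-12)
  expect_true(all(tr_rates$rate[tr_rates$n_events == 0] == 0))
  # rate is monotone in event count at fixed branch length
  expect_true(all(diff(log1p(0:10) / 0.5) > 0))
  # root branch excluded
  expect_false(sp$root %in% rc$rates$node)
})

test_that("epoch comparison controls its type-I error under the null", {
  # constant per-copy rates, equal branch lengths: recent (leaf) and
  # earlier branches share the same event-count distribution
  sp <- balanced_species(16, bl = 1)
  red <- compute_red(sp)
  sig <- 0
  for (rep in 1:100) {
    ds <- simulate_dataset(sp, sim_config(dup_rate = 0.1, transfer_rate = 0,
                                          loss_rate = 0.1, n_families = 40,
                                          seed = 1000 + rep))
    rc <- rate_curves(truth_event_table(ds), red, sp)
    p <- rc$tests$p_value[rc$tests$kind == "duplication"]
    if (!is.na(p) && p < 0.01) sig <- sig + 1
  }
  expect_lte(sig, 5)
})
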