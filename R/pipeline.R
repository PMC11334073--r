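#' Assemble a run configuration
#'
#' Defaults follow the package's standard analysis constants: a cost grid
#' centered on D/T/L = 3:3:1, 100 reconciliation trials per family with
#' median aggregation, RED epoch threshold 0.95, and E-value threshold
#' 1e-3.
#'
#' @param species_newick path to the species tree, or NULL to simulate a
#'   random ultrametric tree with `n_tips` leaves.
#' @param n_tips leaves of the simulated species tree when no Newick is
#'   given.
#' @param n_families families to simulate.
#' @param dup_rate,transfer_rate,loss_rate simulator rates (per copy per
#'   unit branch length).
#' @param costs a [cost_scheme()] (grid center).
#' @param grid optional list of [cost_scheme()]s for a sensitivity run.
#' @param n_trials reconciliation trials per family.
#' @param seed master seed; stage substreams are derived from it.
#' @param epoch_threshold RED split for the rate comparison.
#' @param e_threshold E-value threshold for the prep stage.
#' @param n_lineages lineages to cut the tree into for the vHGT matrix.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(species_newick = NULL, n_tips = 16L,
                       n_families = 300L, dup_rate = 0.1,
                       transfer_rate = 0.1, loss_rate = 0.1,
                       costs = cost_scheme(3, 3, 1), grid = NULL,
                       n_trials = 100L, seed = 1L,
                       epoch_threshold = 0.95, e_threshold = 1e-3,
                       n_lineages = 4L, out_dir = "dtlrecon_run") {
  structure(list(species_newick = species_newick, n_tips = as.integer(n_tips),
                 n_families = as.integer(n_families), dup_rate = dup_rate,
                 transfer_rate = transfer_rate, loss_rate = loss_rate,
                 costs = costs, grid = grid, n_trials = as.integer(n_trials),
                 seed = as.integer(seed), epoch_threshold = epoch_threshold,
                 e_threshold = e_threshold, n_lineages = as.integer(n_lineages),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file; keys are [run_config()] arguments (`costs` and
#'   `grid` given as numeric D/T/L triples).
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$costs)) y$costs <- do.call(cost_scheme, as.list(y$costs))
  if (!is.null(y$grid))
    y$grid <- lapply(y$grid, function(v) do.call(cost_scheme, as.list(v)))
  do.call(run_config, y)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full simulate -> reconcile -> analyze pipeline
#'
#' Deterministic given the config seed: each stage draws from its own
#' substream so stages are independently reproducible. Writes all output
#' tables plus a machine-readable manifest (config echo, file checksums)
#' into `config$out_dir` and returns the in-memory results invisibly.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the species tree, dataset, trials, event
#'   table and all analytics results.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  # -- species tree ----------------------------------------------------------
  if (is.null(config$species_newick)) {
    set.seed(substream_seed(config$seed, 1L))
    phy <- ape::rcoal(config$n_tips,
                      tip.label = paste0("G", seq_len(config$n_tips)))
    species <- as_dtl_tree(phy, "species")
    stage_log("species", "simulated ultrametric tree with %d leaves",
              config$n_tips)
  } else {
    species <- read_newick(config$species_newick, "species")
    stage_log("species", "read %s (%d leaves)", config$species_newick,
              species$n_tips)
  }
  write_newick(species, out("species_tree.nwk"))

  # -- simulate --------------------------------------------------------------
  cfg <- sim_config(dup_rate = config$dup_rate,
                    transfer_rate = config$transfer_rate,
                    loss_rate = config$loss_rate,
                    n_families = config$n_families,
                    seed = substream_seed(config$seed, 2L))
  dataset <- simulate_dataset(species, cfg)
  write_dataset(dataset, config$out_dir)
  stage_log("simulate", "%d families (%d eligible), %d true events",
            config$n_families, sum(dataset$eligible), nrow(dataset$truth))

  # -- reconcile -------------------------------------------------------------
  trials <- reconcile_dataset(dataset, species, config$costs,
                              n_trials = config$n_trials,
                              seed = substream_seed(config$seed, 3L))
  table <- build_event_table(trials, species)
  write_event_table(table, out("events_per_branch.tsv"))
  fam_sum <- do.call(rbind, lapply(trials, function(tr)
    data.frame(family = tr$family, cost = tr$opt_cost,
               t(tr$totals["median", ]), stringsAsFactors = FALSE)))
  utils::write.table(fam_sum, out("family_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_log("reconcile", "%d families reconciled (%s, %d trials)",
            length(trials), format(config$costs), config$n_trials)
  if (!is.null(config$grid)) {
    gs <- cost_grid_run(dataset, species, config$grid,
                        n_trials = config$n_trials,
                        seed = substream_seed(config$seed, 4L))
    utils::write.table(gs, out("grid_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage_log("reconcile", "cost grid: %d schemes", nrow(gs))
  }

  # -- event analytics -------------------------------------------------------
  counts <- ancestral_gene_counts(table)
  utils::write.table(counts, out("ancestral_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lineages <- assign_lineages(species, config$n_lineages)
  utils::write.table(data.frame(leaf = names(lineages), lineage = lineages),
                     out("lineages.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  breakdown <- gain_mechanism_breakdown(table, species, lineages)
  utils::write.table(breakdown, out("breakdown_by_clade.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  traj <- do.call(rbind, lapply(seq_len(species$n_tips), function(l) {
    tr <- per_leaf_trajectory(table, species, l)
    data.frame(leaf = tr$leaf, genes_at_leaf = tr$genes_at_leaf,
               gains = tr$gains, losses = tr$losses)
  }))
  utils::write.table(traj, out("trajectories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_log("events", "total gains %.1f, losses %.1f",
            sum(et_gains(table)), sum(table$losses))

  # -- vHGT statistics -------------------------------------------------------
  transfers <- do.call(rbind, lapply(trials, `[[`, "transfer_pairs"))
  utils::write.table(transfers, out("transfers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vm <- vhgt_matrix(transfers, species, lineages)
  utils::write.table(as.data.frame(vm$freq), out("vhgt_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  prof <- distance_profile(transfers, species)
  utils::write.table(prof, out("distance_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  set.seed(substream_seed(config$seed, 5L))
  hosts <- synthetic_hosts(unique(lineages))
  utils::write.table(hosts, out("hosts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  hov <- tryCatch(host_overlap_test(vm, hosts), error = function(e) NULL)
  prop <- tryCatch(propensities(trials), error = function(e) NULL)
  if (!is.null(prop))
    utils::write.table(prop$records, out("propensities.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  # -- rates -----------------------------------------------------------------
  red <- compute_red(species)
  write_red_tsv(red, out("red.tsv"))
  rc <- rate_curves(table, red, species, threshold = config$epoch_threshold)
  utils::write.table(rc$rates, out("rates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tests <- rc$tests
  tests$test <- "rate_epoch_mwu"
  if (!is.null(hov))
    tests <- rbind(tests,
                   data.frame(kind = "host_overlap", U = hov$U,
                              p_value = hov$p_value, delta = hov$delta,
                              test = "host_overlap_mwu"))
  utils::write.table(tests, out("tests.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stage_log("rates", "epoch split at RED >= %g", config$epoch_threshold)

  # -- manifest --------------------------------------------------------------
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    config = config_echo(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("dtlrecon")),
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  stage_log("done", "outputs in %s", config$out_dir)

  invisible(list(species = species, dataset = dataset, trials = trials,
                 table = table, counts = counts, breakdown = breakdown,
                 vhgt = vm, profile = prof, host_test = hov,
                 propensities = prop, red = red, rates = rc,
                 manifest = manifest))
}

config_echo <- function(config) {
  e <- unclass(config)
  e$costs <- unlist(unclass(e$costs))
  if (!is.null(e$grid)) e$grid <- lapply(e$grid, function(g) unlist(unclass(g)))
  e
}

# simple synthetic host annotation: each lineage infects 1-2 phyla from a
# small pool, guaranteeing both overlapping and disjoint pairs when
# enough lineages exist
synthetic_hosts <- function(lineages,
                            pool = c("Amoebozoa", "Chlorophyta",
                                     "Haptophyta", "Arthropoda",
                                     "Chordata")) {
  rows <- lapply(seq_along(lineages), function(i) {
    k <- sample(1:2, 1)
    data.frame(lineage = lineages[i],
               host_phylum = sample(pool, k),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
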