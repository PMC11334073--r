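#' Classify orthogroups as viral-specific
#'
#' An orthogroup is viral-specific iff none of its members has a hit
#' against a cellular-organism database below the E-value threshold.
#' Lowering the threshold can only move families towards viral-specific
#' (monotonicity). Genes present in the hit table but in no orthogroup
#' are ignored with a warning.
#'
#' @param membership data.frame `gene`, `family`.
#' @param hits data.frame `query`, `subject`, `evalue`, `bitscore`, `db`
#'   (rows tagged `"cellular"` are the ones that matter here).
#' @param e_threshold E-value cutoff (default 1e-3; hits at exactly the
#'   threshold do not count).
#' @return data.frame `family`, `label` in
#'   {`viral_specific`, `nonviral_specific`}.
#' @export
classify_viral_specific <- function(membership, hits, e_threshold = 1e-3) {
  stray <- setdiff(unique(hits$query), membership$gene)
  if (length(stray))
    warning("ignoring hits for ", length(stray),
            " gene(s) absent from the orthogroup membership: ",
            paste(utils::head(stray, 3), collapse = ", "))
  cell <- hits[hits$db == "cellular" & hits$evalue < e_threshold, ,
               drop = FALSE]
  flagged <- unique(membership$family[membership$gene %in% cell$query])
  fams <- unique(membership$family)
  data.frame(family = fams,
             label = ifelse(fams %in% flagged, "nonviral_specific",
                            "viral_specific"),
             stringsAsFactors = FALSE)
}

#' Assign a functional category to each orthogroup
#'
#' Each member gene's best GVOG is its maximum-bitscore hit below the
#' E-value threshold; the orthogroup is assigned the GVOG with the most
#' best hits (plurality vote), and that GVOG's EggNOG-style category
#' letter. Ties are broken by the lexicographically smallest GVOG
#' identifier and flagged. Families without any qualifying hit are
#' `uncharacterized`.
#'
#' @param membership data.frame `gene`, `family`.
#' @param hits data.frame `query`, `subject` (GVOG id), `evalue`,
#'   `bitscore`, typically `db == "gvog"` rows.
#' @param category_map data.frame `gvog`, `category`.
#' @param e_threshold E-value cutoff (default 1e-3).
#' @return data.frame `family`, `gvog`, `category`, `tie`.
#' @export
assign_function <- function(membership, hits, category_map,
                            e_threshold = 1e-3) {
  if (!is.null(hits$db)) hits <- hits[hits$db == "gvog", , drop = FALSE]
  hits <- hits[hits$evalue < e_threshold, , drop = FALSE]
  best <- do.call(rbind, lapply(split(hits, hits$query), function(h) {
    h <- h[order(-h$bitscore, h$subject), , drop = FALSE]
    h[1, c("query", "subject"), drop = FALSE]
  }))
  rows <- lapply(unique(membership$family), function(f) {
    genes <- membership$gene[membership$family == f]
    gv <- best$subject[best$query %in% genes]
    if (length(gv) == 0)
      return(data.frame(family = f, gvog = NA_character_,
                        category = "uncharacterized", tie = FALSE,
                        stringsAsFactors = FALSE))
    tab <- sort(table(gv), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    tie <- length(top) > 1
    g <- sort(top)[1]
    if (tie)
      message("function assignment tie in ", f, ": ",
              paste(sort(top), collapse = " vs "), " -> ", g)
    cat_i <- match(g, category_map$gvog)
    data.frame(family = f, gvog = g,
               category = if (is.na(cat_i)) "uncharacterized"
                          else category_map$category[cat_i],
               tie = tie, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plan intron-aware merging of fragmented genes
#'
#' Within each orthogroup the longest member sequence is the reference;
#' members of the same genome that hit the reference (E-value below the
#' threshold) and are neighbors in genomic order (fewer than 4 intervening
#' genes) are chained greedily left-to-right, with at most 4 genes per
#' merged unit. Never merges across genomes; re-running on a merged
#' membership is a no-op (merged units carry no hits or ordinals).
#'
#' @param membership data.frame `gene`, `family`, `genome`.
#' @param gene_order data.frame `genome`, `gene`, `ordinal` (consecutive
#'   from 0 within each genome, linear -- no circular wraparound).
#' @param lengths data.frame `gene`, `length` (sequence lengths, used to
#'   pick the reference).
#' @param hits data.frame `query`, `subject`, `evalue`: member-vs-member
#'   hits within orthogroups (the rows where `subject` is the reference
#'   are used).
#' @param e_threshold E-value cutoff (default 1e-3).
#' @param max_gap maximum intervening genes is `max_gap - 1` (default 4,
#'   i.e. "< 4 genes between them").
#' @param max_merge maximum genes per merged unit (default 4).
#' @return list: `plan` (data.frame family, genome, unit, gene, position;
#'   only units with >= 2 genes), `membership` (updated, merged units
#'   named `g1+g2+...`), `references` (per family).
#' @export
merge_fragments <- function(membership, gene_order, lengths, hits,
                            e_threshold = 1e-3, max_gap = 4L,
                            max_merge = 4L) {
  ord <- stats::setNames(gene_order$ordinal, gene_order$gene)
  len <- stats::setNames(lengths$length, lengths$gene)
  plan <- list(); refs <- list()
  new_membership <- membership
  for (f in unique(membership$family)) {
    mem <- membership[membership$family == f, , drop = FALSE]
    ln <- len[mem$gene]
    if (all(is.na(ln))) next
    cand_ref <- mem$gene[!is.na(ln) & ln == max(ln, na.rm = TRUE)]
    if (length(cand_ref) > 1)
      message("reference length tie in ", f, ": picking ", sort(cand_ref)[1])
    ref <- sort(cand_ref)[1]
    refs[[f]] <- ref
    hit_ok <- hits$query[hits$subject == ref & hits$evalue < e_threshold]
    members <- mem$gene[(mem$gene %in% hit_ok | mem$gene == ref) &
                          mem$gene %in% names(ord)]
    for (g in unique(mem$genome[mem$gene %in% members])) {
      gg <- members[mem$genome[match(members, mem$gene)] == g]
      gg <- gg[order(ord[gg])]
      if (length(gg) < 2) next
      unit <- 1L; chain <- gg[1]
      flush <- function(chain, unit) {
        if (length(chain) >= 2)
          plan[[length(plan) + 1L]] <<- data.frame(
            family = f, genome = g,
            unit = paste0(f, "_", g, "_m", unit),
            gene = chain, position = seq_along(chain),
            stringsAsFactors = FALSE)
      }
      for (i in seq_along(gg)[-1]) {
        gap <- ord[gg[i]] - ord[chain[length(chain)]] - 1
        if (gap < max_gap && length(chain) < max_merge) {
          chain <- c(chain, gg[i])
        } else {
          flush(chain, unit); unit <- unit + 1L; chain <- gg[i]
        }
      }
      flush(chain, unit)
    }
  }
  plan <- if (length(plan)) do.call(rbind, plan) else
    data.frame(family = character(0), genome = character(0),
               unit = character(0), gene = character(0),
               position = integer(0))
  if (nrow(plan)) {
    for (u in unique(plan$unit)) {
      genes <- plan$gene[plan$unit == u]
      first <- match(genes[1], new_membership$gene)
      new_membership$gene[first] <- paste(genes, collapse = "+")
      new_membership <- new_membership[!(new_membership$gene %in% genes[-1]), ,
                                       drop = FALSE]
    }
    rownames(new_membership) <- NULL
  }
  list(plan = plan, membership = new_membership,
       references = unlist(refs))
}
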