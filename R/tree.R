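#' Read a rooted binary tree from a Newick string or file
#'
#' Parses Newick text into the package's tree container. Trees must be
#' rooted and strictly binary: multifurcations are rejected (a
#' non-bifurcating tree cannot be reconciled under the binary DTL model),
#' as are duplicate leaf labels and negative branch lengths. Missing
#' branch lengths default to 0 with a warning. Internal node labels, when
#' present, are kept as plain names (they are never interpreted as
#' support values).
#'
#' For `kind = "gene"` every leaf label must have the form
#' `"<genome>|<gene>"`; the genome part is what reconciliation maps onto
#' species-tree leaves.
#'
#' Node identifiers are deterministic functions of the Newick text
#' (tips are numbered 1..n in order of appearance, internal nodes from
#' n+1 starting at the root), so all downstream tables are diffable
#' across runs.
#'
#' @param text a Newick string, or a path to a file containing one tree.
#' @param kind `"species"` or `"gene"`.
#' @return an object of class `dtl_tree` (and `species_tree` or
#'   `gene_tree`), a list with elements `phylo` (the [ape::read.tree()]
#'   result), `parent`, `children`, `branch_length`, `root`, `n_tips`,
#'   `n_nodes`, `postorder`, `node_name`, and for gene trees `genome`
#'   (leaf -> genome identifier).
#' @export
read_newick <- function(text, kind = c("species", "gene")) {
  kind <- match.arg(kind)
  if (length(text) == 1 && !grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("unparsable Newick string", call. = FALSE)
  as_dtl_tree(phy, kind)
}

# cheap structural pre-check so syntax errors carry a character offset
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("unparsable Newick: unbalanced ')' at character %d", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("unparsable Newick: %d unclosed '(' at character %d",
                 depth, length(chars)), call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop(sprintf("unparsable Newick: missing terminal ';' at character %d",
                 nchar(text)), call. = FALSE)
  invisible(TRUE)
}

#' @rdname read_newick
#' @param phy an [ape::phylo] object already in memory.
#' @export
as_dtl_tree <- function(phy, kind = c("species", "gene")) {
  kind <- match.arg(kind)
  stopifnot(inherits(phy, "phylo"))
  n_tips <- length(phy$tip.label)
  if (n_tips < 2) stop("tree must have at least 2 leaves", call. = FALSE)
  n_nodes <- n_tips + phy$Nnode

  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf label: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "), call. = FALSE)

  if (is.null(phy$edge.length)) {
    warning("no branch lengths in Newick input; defaulting to 0")
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (any(is.na(phy$edge.length)))
    phy$edge.length[is.na(phy$edge.length)] <- 0
  if (any(phy$edge.length < 0))
    stop("negative branch length", call. = FALSE)

  parent <- integer(n_nodes)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- n_tips + 1L
  parent[root] <- 0L

  kids <- vector("list", n_nodes)
  for (k in seq_len(nrow(phy$edge)))
    kids[[phy$edge[k, 1]]] <- c(kids[[phy$edge[k, 1]]], phy$edge[k, 2])

  n_children <- lengths(kids)
  bad <- which(n_children != 0L & n_children != 2L)
  if (length(bad)) {
    node <- bad[1]
    tips <- tip_set(kids, node, n_tips)
    stop(sprintf("multifurcation (or unary node) at node %d [%d children; leaves: %s]",
                 node, n_children[node],
                 paste(utils::head(phy$tip.label[tips], 4), collapse = ",")),
         call. = FALSE)
  }

  bl <- numeric(n_nodes)
  bl[phy$edge[, 2]] <- phy$edge.length
  bl[root] <- if (!is.null(phy$root.edge)) phy$root.edge else 0

  node_name <- character(n_nodes)
  node_name[seq_len(n_tips)] <- phy$tip.label
  if (!is.null(phy$node.label) && length(phy$node.label) == phy$Nnode &&
      all(nzchar(phy$node.label))) {
    node_name[(n_tips + 1L):n_nodes] <- phy$node.label
  } else {
    node_name[(n_tips + 1L):n_nodes] <-
      paste0("n", (n_tips + 1L):n_nodes)
  }

  tr <- structure(list(
    phylo = phy, parent = parent, children = kids,
    branch_length = bl, root = root, n_tips = n_tips, n_nodes = n_nodes,
    postorder = postorder_nodes(kids, root),
    node_name = node_name
  ), class = c(paste0(kind, "_tree"), "dtl_tree"))

  if (kind == "gene") {
    lab <- phy$tip.label
    if (!all(grepl("|", lab, fixed = TRUE)))
      stop("gene-tree leaf labels must look like '<genome>|<gene>'; offender: ",
           lab[!grepl("|", lab, fixed = TRUE)][1], call. = FALSE)
    tr$genome <- sub("\\|.*$", "", lab)
  }
  tr
}

tip_set <- function(kids, node, n_tips) {
  if (node <= n_tips) return(node)
  unlist(lapply(kids[[node]], tip_set, kids = kids, n_tips = n_tips))
}

postorder_nodes <- function(kids, root) {
  # iterative to avoid deep recursion limits on caterpillar trees
  stack <- c(root)
  visited <- integer(0)
  seen <- logical(length(kids))
  while (length(stack)) {
    v <- stack[length(stack)]
    if (!seen[v] && length(kids[[v]])) {
      seen[v] <- TRUE
      stack <- c(stack, rev(kids[[v]]))
    } else {
      visited <- c(visited, v)
      stack <- stack[-length(stack)]
    }
  }
  visited
}

#' Write a tree back to Newick
#'
#' Round-trips losslessly for topology, leaf labels and branch lengths
#' (to printed precision).
#'
#' @param tree a `dtl_tree`.
#' @param file optional path; when `NULL` the string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "dtl_tree"))
  s <- ape::write.tree(tree$phylo)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' @export
print.dtl_tree <- function(x, ...) {
  cat(sprintf("<%s> %d leaves, %d nodes, total length %.4g\n",
              class(x)[1], x$n_tips, x$n_nodes, sum(x$branch_length)))
  invisible(x)
}

# -- node utilities ----------------------------------------------------------

resolve_node <- function(tree, node) {
  if (is.character(node)) {
    i <- match(node, tree$node_name)
    if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
    return(i)
  }
  node <- as.integer(node)
  if (any(node < 1L | node > tree$n_nodes))
    stop("unknown node id: ", node[node < 1L | node > tree$n_nodes][1],
         call. = FALSE)
  node
}

is_leaf <- function(tree, node) node <= tree$n_tips

#' Node depths (root-to-node path lengths)
#' @param tree a `dtl_tree`.
#' @return numeric vector over node ids, in branch-length units from the root.
#' @export
node_depths <- function(tree) {
  d <- numeric(tree$n_nodes)
  for (v in rev(tree$postorder)) {        # preorder
    p <- tree$parent[v]
    d[v] <- if (p == 0L) 0 else d[p] + tree$branch_length[v]
  }
  d
}

ancestor_chain <- function(tree, node) {
  ch <- node
  while (tree$parent[node] != 0L) {
    node <- tree$parent[node]
    ch <- c(ch, node)
  }
  ch
}

# anc_mat[a, d] TRUE iff a is a strict ancestor of d
ancestor_matrix <- function(tree) {
  m <- matrix(FALSE, tree$n_nodes, tree$n_nodes)
  for (v in seq_len(tree$n_nodes)) {
    ch <- ancestor_chain(tree, v)
    if (length(ch) > 1) m[ch[-1], v] <- TRUE
  }
  m
}

# tips below each node (list over node ids)
tips_below <- function(tree) {
  out <- vector("list", tree$n_nodes)
  for (v in tree$postorder) {
    out[[v]] <- if (is_leaf(tree, v)) v else
      unlist(out[tree$children[[v]]], use.names = FALSE)
  }
  out
}

#' Patristic distance between two nodes
#'
#' Sum of branch lengths along the unique path between `a` and `b`
#' (either node ids or node names). Symmetric; zero iff `a == b`.
#'
#' @param tree a `dtl_tree`.
#' @param a,b node ids or names.
#' @export
patristic_distance <- function(tree, a, b) {
  a <- resolve_node(tree, a); b <- resolve_node(tree, b)
  if (a == b) return(0)
  d <- node_depths(tree)
  ca <- ancestor_chain(tree, a)
  cb <- ancestor_chain(tree, b)
  mrca <- ca[match(TRUE, ca %in% cb)]
  d[a] + d[b] - 2 * d[mrca]
}

# full node-to-node distance matrix (ape)
node_distance_matrix <- function(tree) ape::dist.nodes(tree$phylo)

#' Relative evolutionary divergence (RED)
#'
#' Computes RED for every node of a rooted tree: the root has RED 0,
#' leaves have RED 1, and an internal node `v` with parent `p` gets
#' `red(v) = red(p) + (d/u) * (1 - red(p))` where `d` is the length of
#' the branch above `v` and `u` is the mean patristic distance from `p`
#' to the leaves descending through `v` (i.e. `d` plus the mean
#' node-to-leaf distance of `v`). RED interpolates divergence between the
#' root (0) and the present (1) and is monotone along root-to-leaf paths
#' when all branch lengths are positive.
#'
#' @param tree a `species_tree`.
#' @return a data.frame with columns `node`, `node_name`, `red`.
#' @export
compute_red <- function(tree) {
  stopifnot(inherits(tree, "dtl_tree"))
  n <- tree$n_nodes
  ntips_v <- integer(n); sumdist <- numeric(n)
  for (v in tree$postorder) {
    if (is_leaf(tree, v)) { ntips_v[v] <- 1L; sumdist[v] <- 0 }
    else {
      for (c in tree$children[[v]]) {
        ntips_v[v] <- ntips_v[v] + ntips_v[c]
        sumdist[v] <- sumdist[v] + sumdist[c] +
          tree$branch_length[c] * ntips_v[c]
      }
    }
  }
  red <- numeric(n)
  for (v in rev(tree$postorder)) {        # preorder
    p <- tree$parent[v]
    if (p == 0L) { red[v] <- 0; next }
    if (is_leaf(tree, v)) { red[v] <- 1; next }
    d <- tree$branch_length[v]
    u <- d + sumdist[v] / ntips_v[v]
    if (u <= 0)
      stop(sprintf("RED undefined at node %d: zero mean distance to leaves (all-zero subtree lengths)", v),
           call. = FALSE)
    red[v] <- red[p] + (d / u) * (1 - red[p])
  }
  data.frame(node = seq_len(n), node_name = tree$node_name, red = red)
}

#' Write a RED table as TSV (`node_id  node_name  red`)
#' @param red data.frame from [compute_red()].
#' @param file output path.
#' @export
write_red_tsv <- function(red, file) {
  utils::write.table(red, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
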