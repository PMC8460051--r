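#' Rooted trees with indexed edges
#'
#' A `rooted_tree` wraps an [ape::phylo] object that is strictly binary and
#' rooted, and augments it with a deterministic post-order edge index.  Edges
#' are numbered `1..2n-2`; the reserved index `0` denotes "no mutation" and is
#' written as the Greek epsilon in the model formulas.  Every non-root node
#' owns the edge above it, and `tip_clade()` returns the tips below an edge.
#'
#' @param phy an [ape::phylo] object (rooted, binary, unique tip labels).
#' @return an object of class `rooted_tree`: a list with elements `phy`
#'   (the phylo, reordered in post-order), `n_tips`, `tip_labels`, `n_edges`
#'   (`2n - 2`), `node_of_edge` (phylo node id below each indexed edge) and
#'   `clades` (logical matrix, one row per edge, one column per tip).
#' @export
as_rooted_tree <- function(phy) {
  if (inherits(phy, "rooted_tree")) return(phy)
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape 'phylo' object")
  n <- length(phy$tip.label)
  if (n < 3L) stop("a rooted_tree needs at least 3 tips, got ", n)
  if (anyDuplicated(phy$tip.label)) {
    dup <- phy$tip.label[duplicated(phy$tip.label)][1L]
    stop("duplicate tip label: '", dup, "'")
  }
  if (!ape::is.rooted(phy)) stop("tree is not rooted")
  ## strict binarity: every internal node (root included) has exactly 2 children
  kids <- tabulate(phy$edge[, 1L], nbins = n + phy$Nnode)
  bad <- which(kids[(n + 1L):(n + phy$Nnode)] != 2L) + n
  if (length(bad)) {
    stop("non-binary node: node ", bad[1L], " has ",
         kids[bad[1L]], " children (need exactly 2)")
  }
  phy <- ape::reorder.phylo(phy, "postorder")
  n_edges <- 2L * n - 2L
  stopifnot(nrow(phy$edge) == n_edges)
  ## edge u is row u of the post-order edge matrix; the node below it:
  node_of_edge <- phy$edge[, 2L]
  clades <- matrix(FALSE, n_edges, n, dimnames = list(NULL, phy$tip.label))
  for (u in seq_len(n_edges)) {
    child <- node_of_edge[u]
    if (child <= n) {
      clades[u, child] <- TRUE
    } else {
      ## post-order guarantees the child's own edges precede u
      sub <- which(phy$edge[, 1L] == child)
      clades[u, ] <- clades[sub[1L], ] | clades[sub[2L], ]
    }
  }
  structure(
    list(phy = phy, n_tips = n, tip_labels = phy$tip.label,
         n_edges = n_edges, node_of_edge = node_of_edge, clades = clades),
    class = "rooted_tree"
  )
}

#' Parse a rooted binary newick string
#'
#' Strict parser for the trees the model works with: rooted, strictly binary,
#' at least three uniquely labelled tips.  Branch lengths are optional and
#' preserved.  Edge indexing is post-order and deterministic, so repeated
#' parses of the same string yield identical indices.
#'
#' @param text a newick string (terminating `;` optional).
#' @return a [as_rooted_tree()] object.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' tr$n_edges  # 4
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("malformed newick near: '",
         substr(trimws(text), 1L, 40L), "'")
  }
  as_rooted_tree(phy)
}

#' Write a rooted tree as newick
#'
#' @param tree a `rooted_tree` (or `phylo`).
#' @param digits significant digits for branch lengths.
#' @return a newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  phy <- if (inherits(tree, "rooted_tree")) tree$phy else tree
  ape::write.tree(phy, digits = digits)
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("<rooted_tree> ", x$n_tips, " tips, ", x$n_edges,
      " indexed edges (post-order)\n", sep = "")
  cat("  ", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Tips below an edge
#'
#' @param tree a `rooted_tree`.
#' @param u edge index in `1..2n-2` (index 0, "no mutation", has no clade).
#' @return character vector of tip labels descending from edge `u`.
#' @export
tip_clade <- function(tree, u) {
  tree <- as_rooted_tree(tree)
  if (!is.numeric(u) || length(u) != 1L || u != as.integer(u) ||
      u < 1L || u > tree$n_edges) {
    stop("edge index out of range: u = ", u,
         " (valid: 1..", tree$n_edges, ")")
  }
  tree$tip_labels[tree$clades[u, ]]
}

#' Edge index above a clade
#'
#' Inverse of [tip_clade()]: find the edge whose clade is exactly `tips`.
#'
#' @param tree a `rooted_tree`.
#' @param tips character vector of tip labels.
#' @return the edge index, or an error if no edge subtends exactly this set.
#' @export
edge_above <- function(tree, tips) {
  tree <- as_rooted_tree(tree)
  want <- tree$tip_labels %in% tips
  if (sum(want) != length(unique(tips))) {
    stop("unknown tip label(s): ",
         paste(setdiff(tips, tree$tip_labels), collapse = ", "))
  }
  hit <- which(apply(tree$clades, 1L, function(cl) all(cl == want)))
  if (length(hit) != 1L) stop("no edge subtends exactly {",
                              paste(tips, collapse = ","), "}")
  hit
}

## Canonical unrooted split keys of a tree, after applying a label mapping.
## Each split is the tip-side set written through `map`, represented by the
## lexicographically smaller of the two sides so orientation does not matter.
## Trivial splits (single tips) are included; they encode the tip set itself.
unrooted_split_keys <- function(tree, map = NULL) {
  tree <- as_rooted_tree(tree)
  labs <- tree$tip_labels
  if (!is.null(map)) labs <- unname(map[labs])
  keys <- character(0)
  for (u in seq_len(tree$n_edges)) {
    side <- sort(labs[tree$clades[u, ]])
    other <- sort(labs[!tree$clades[u, ]])
    k1 <- paste(side, collapse = "\r")
    k2 <- paste(other, collapse = "\r")
    keys <- c(keys, if (k1 < k2) k1 else k2)
  }
  unique(keys)
}

#' Unrooted topological identity under a tip mapping
#'
#' Two rooted trees are compared as unrooted topologies: `TRUE` iff the split
#' sets induced by their edges coincide once the tips of `t1` are renamed
#' through `mapping`.  This is the identity used when scoring an estimated
#' tree against a reference tree whose tip names differ.
#'
#' @param t1,t2 `rooted_tree` objects with the same number of tips.
#' @param mapping named character vector mapping every tip label of `t1` to a
#'   tip label of `t2`; must be a bijection.  Defaults to the identity.
#' @return logical scalar.
#' @examples
#' a <- parse_newick("((A,B),(C,D));")
#' b <- parse_newick("((A,C),(B,D));")
#' unrooted_equal(a, a)  # TRUE
#' unrooted_equal(a, b)  # FALSE
#' @export
unrooted_equal <- function(t1, t2, mapping = NULL) {
  t1 <- as_rooted_tree(t1); t2 <- as_rooted_tree(t2)
  if (t1$n_tips != t2$n_tips) stop("trees have different numbers of tips")
  if (is.null(mapping)) {
    mapping <- stats::setNames(t1$tip_labels, t1$tip_labels)
  }
  if (is.null(names(mapping)) ||
      !setequal(names(mapping), t1$tip_labels) ||
      !setequal(unname(mapping), t2$tip_labels) ||
      anyDuplicated(unname(mapping))) {
    stop("`mapping` must be a bijection from the tips of t1 onto the tips of t2")
  }
  k1 <- unrooted_split_keys(t1, map = mapping)
  k2 <- unrooted_split_keys(t2)
  setequal(k1, k2)
}

## ---- lightweight topology representation used by the sampler -------------
##
## parent: integer vector over nodes 1..2n-1 (tips are 1..n), 0 at the root.
## children: 2 x (2n-1) matrix, 0 for tips.  Cheap to clone and to mutate.

tree_to_struct <- function(tree) {
  tree <- as_rooted_tree(tree)
  phy <- tree$phy
  n <- tree$n_tips
  m <- n + phy$Nnode
  parent <- integer(m)
  children <- matrix(0L, 2L, m)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    parent[c] <- p
    children[if (children[1L, p] == 0L) 1L else 2L, p] <- c
  }
  list(parent = parent, children = children,
       root = which(parent == 0L), n_tips = n,
       tip_labels = tree$tip_labels)
}

struct_to_phylo <- function(st) {
  n <- st$n_tips
  m <- length(st$parent)
  nonroot <- setdiff(seq_len(m), st$root)
  edge <- cbind(st$parent[nonroot], nonroot)
  phy <- list(edge = edge, Nnode = m - n,
              tip.label = st$tip_labels %||% paste0("T", seq_len(n)))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ## ape requires internal node numbers > n and root = n+1 convention; our
  ## structs (coming from phylo or random joins) may violate the numbering,
  ## so renumber canonically: tips keep 1..n, internals relabelled in a
  ## traversal order with the root first.
  renumber_phylo(phy, n, st$root)
}

renumber_phylo <- function(phy, n, root) {
  m <- n + phy$Nnode
  new_id <- integer(m)
  new_id[seq_len(n)] <- seq_len(n)
  ## breadth-first from root over internal nodes
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  queue <- root; nxt <- n + 1L
  while (length(queue)) {
    node <- queue[[1L]]; queue <- queue[-1L]
    new_id[node] <- nxt; nxt <- nxt + 1L
    for (k in kids[[as.character(node)]]) {
      if (k > n) queue <- c(queue, k)
    }
  }
  phy$edge <- cbind(new_id[phy$edge[, 1L]], new_id[phy$edge[, 2L]])
  ape::reorder.phylo(phy, "postorder")
}

## clade matrix (rows: post-order edges 1..2n-2) straight from a struct
struct_clades <- function(st) {
  n <- st$n_tips
  m <- length(st$parent)
  ## post-order over nodes
  ord <- integer(0)
  stack <- st$root
  while (length(stack)) {
    node <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    ord <- c(node, ord)
    if (node > 0L && st$children[1L, node] != 0L) {
      stack <- c(stack, st$children[1L, node], st$children[2L, node])
    }
  }
  ord <- ord[ord != st$root]
  below <- matrix(FALSE, m, n)
  for (t in seq_len(n)) below[t, t] <- TRUE
  ## fill internals bottom-up (ord is post-order so children come first)
  for (node in ord) {
    if (st$children[1L, node] != 0L) {
      below[node, ] <- below[st$children[1L, node], ] |
        below[st$children[2L, node], ]
    }
  }
  if (st$children[1L, st$root] != 0L) {
    below[st$root, ] <- TRUE
  }
  ## edges indexed by position of their lower node in post-order
  below[ord, , drop = FALSE]
}

## uniform-ish random labelled rooted binary topology by sequential joins
random_struct <- function(n, tip_labels = paste0("T", seq_len(n))) {
  m <- 2L * n - 1L
  parent <- integer(m)
  children <- matrix(0L, 2L, m)
  avail <- seq_len(n)
  nxt <- n + 1L
  while (length(avail) > 1L) {
    pick <- sample(length(avail), 2L)
    a <- avail[pick[1L]]; b <- avail[pick[2L]]
    parent[c(a, b)] <- nxt
    children[, nxt] <- c(a, b)
    avail <- c(avail[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, children = children, root = m, n_tips = n,
       tip_labels = tip_labels)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
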