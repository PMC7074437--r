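#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion and branch-length
#' formulas. Two implementation details make the result bit-reproducible
#' across runs, platforms and input orderings:
#' \itemize{
#'   \item exact ties in Q are broken by joining the pair whose (sorted)
#'     current node labels are lexicographically smallest; the label of a
#'     merged node is the smaller of its children's labels;
#'   \item a negative branch length is clamped to 0 and the deficit moved to
#'     its sibling edge, keeping the pair's total length equal to their
#'     distance.
#' }
#' For two taxa the tree is the single path of total length `d(1,2)`; the
#' final three nodes are joined onto one trifurcating root surrogate with the
#' three-taxon closed-form lengths, so the returned tree is unrooted.
#'
#' @param D A `plant_dist`, `dist` or symmetric numeric matrix with unique
#'   row/column names and no undefined entries.
#' @return An [ape][ape::read.tree] `phylo` object (unrooted).
#' @export
nj_tree <- function(D) {
  d <- dist_input(D)
  n <- nrow(d)
  labels <- rownames(d)
  if (n < 2) stop("need at least 2 taxa")
  if (anyNA(d)) stop("distance matrix has undefined entries")
  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
                 tip.label = labels, Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "order") <- "cladewise"
    return(tree)
  }
  # temp node ids: tips 1..n, internals n+1, n+2, ...
  active <- seq_len(n)
  lab <- labels
  next_id <- n + 1L
  parent <- child <- integer(0)
  elen <- numeric(0)
  Dm <- d
  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    mn <- min(Q)
    cand <- which(Q == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(lab[cand[, 1]], lab[cand[, 2]])
    key2 <- pmax(lab[cand[, 1]], lab[cand[, 2]])
    pick <- order(key1, key2, method = "radix")[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    dij <- Dm[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- dij; bi <- 0 }
    if (bj < 0) { bi <- dij; bj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    parent <- c(parent, u, u)
    child <- c(child, active[i], active[j])
    elen <- c(elen, bi, bj)
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- (Dm[i, others] + Dm[j, others] - dij) / 2
    Dm <- rbind(cbind(Dm[others, others, drop = FALSE], dnew),
                c(dnew, 0))
    active <- c(active[others], u)
    lab <- c(lab[others], min(lab[c(i, j)]))
  }
  if (length(active) == 3) {
    d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
    b <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
           (d13 + d23 - d12) / 2)
    b <- pmax(b, 0)
    u <- next_id; next_id <- next_id + 1L
    parent <- c(parent, u, u, u)
    child <- c(child, active)
    elen <- c(elen, b)
  } else { # exactly 2 left can only happen for n == 3 joined already; guard
    u <- next_id; next_id <- next_id + 1L
    parent <- c(parent, u, u)
    child <- c(child, active)
    elen <- c(elen, Dm[1, 2] / 2, Dm[1, 2] / 2)
  }
  build_phylo(parent, child, elen, labels, root = u)
}

# Renumber a parent/child edge list (tips 1..n, arbitrary internal ids,
# given root) into a valid cladewise ape "phylo" object.
build_phylo <- function(parent, child, elen, tip_labels, root,
                        node_labels = NULL) {
  n <- length(tip_labels)
  kids <- split(seq_along(parent), parent)
  n_internal <- length(unique(parent))
  new_id <- integer(max(c(parent, child)))
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n
  edge <- matrix(0L, length(parent), 2)
  edge_len <- numeric(length(parent))
  node_lab_out <- character(n_internal)
  k <- 0L
  # iterative preorder DFS from the root
  stack <- list(root)
  new_id[root] <- counter <- counter + 1L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (e in kids[[as.character(v)]]) {
      ch <- child[e]
      if (ch > n) {
        new_id[ch] <- counter <- counter + 1L
        stack[[length(stack) + 1L]] <- ch
      }
      k <- k + 1L
      edge[k, ] <- c(new_id[v], new_id[ch])
      edge_len[k] <- elen[e]
    }
  }
  tree <- list(edge = edge, edge.length = edge_len,
               tip.label = tip_labels, Nnode = n_internal)
  if (!is.null(node_labels)) {
    lab <- character(n_internal)
    for (old in as.integer(names(node_labels)))
      lab[new_id[old] - n] <- node_labels[[as.character(old)]]
    tree$node.label <- lab
  }
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  ape::reorder.phylo(tree, "cladewise")
}

dist_input <- function(D) {
  if (inherits(D, "plant_dist")) D <- D$d
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  D
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every pair of leaves.
#' Patristic distances are invariant to where the tree is (re)rooted.
#'
#' @param tree A `phylo` object.
#' @param plants Optional character vector giving the row/column order of the
#'   result (defaults to the tree's tip-label order).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
patristic <- function(tree, plants = NULL) {
  stopifnot(inherits(tree, "phylo"))
  P <- ape::cophenetic.phylo(tree)
  ord <- if (is.null(plants)) tree$tip.label else plants
  if (!all(ord %in% rownames(P))) stop("unknown plant in `plants`")
  P[ord, ord]
}

#' Neighbor-joining tree with bootstrap support values
#'
#' Builds the full-data NJ tree, then resamples loci (columns) with
#' replacement `replicates` times, recomputing the distance matrix and NJ
#' tree for each replicate, and annotates every internal edge of the
#' full-data tree with the percentage of replicate trees containing the same
#' leaf bipartition. Resampling loci (not plants) is the standard
#' phylogenetic bootstrap for concatenated marker data. Deterministic for a
#' given seed.
#'
#' In a bootstrap replicate a plant pair can lose all of its shared called
#' loci; such pairs fall back to mean imputation inside the replicate so the
#' replicate tree is still defined.
#'
#' @param x A `geno_matrix` with at least 3 plants.
#' @param replicates Number of bootstrap replicates; default 500.
#' @param seed Integer RNG seed.
#' @param method Distance method passed to [snp_distance_matrix()].
#' @return The full-data `phylo` tree with `node.label` holding support
#'   percentages in `[0, 100]` (empty at the root surrogate).
#' @export
bootstrap_support <- function(x, replicates = 500, seed = 1,
                              method = "allele_sharing") {
  stopifnot(inherits(x, "geno_matrix"))
  if (replicates < 1) stop("replicates must be >= 1")
  if (nrow(x$calls) < 3) stop("need at least 3 plants for bootstrap support")
  full <- nj_tree(snp_distance_matrix(x, method = method))
  target <- tree_splits(full)
  counts <- stats::setNames(numeric(length(target$keys)), target$keys)
  L <- ncol(x$calls)
  set.seed(seed)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    xb <- x
    xb$calls <- x$calls[, cols, drop = FALSE]
    db <- suppressWarnings(
      snp_distance_matrix(xb, method = method, allow_missing_pairs = TRUE))
    tb <- nj_tree(db)
    hit <- unique(tree_splits(tb)$keys)
    present <- hit[hit %in% names(counts)]
    counts[present] <- counts[present] + 1
  }
  support <- 100 * counts / replicates
  labs <- as.list(rep("", full$Nnode))
  names(labs) <- as.character(seq_len(full$Nnode) + length(full$tip.label))
  for (k in seq_along(target$keys)) {
    node <- target$nodes[k]
    labs[[as.character(node)]] <- format_support(support[k])
  }
  full$node.label <- unname(unlist(labs))
  full
}

format_support <- function(s) {
  if (abs(s - round(s)) < 1e-9) as.character(round(s)) else sprintf("%.1f", s)
}

# Non-trivial bipartitions of an unrooted tree, keyed canonically by the
# sorted tip labels of the side not containing the alphabetically first tip.
# Returns the internal node under each split (for node.label annotation).
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  desc <- descendant_tips(tree)
  nodes <- setdiff(seq_len(tree$Nnode) + n, root)
  keys <- character(0)
  keep_nodes <- integer(0)
  ref <- sort(tree$tip.label)[1]
  for (v in nodes) {
    side <- tree$tip.label[desc[[v]]]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = ";"))
    keep_nodes <- c(keep_nodes, v)
  }
  list(keys = keys, nodes = keep_nodes)
}

# tips below each node (list indexed by node id)
descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  edge <- tree$edge
  # postorder: process edges from last to first in cladewise order
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] that preserve
#' topology, branch lengths (10 significant digits) and internal-node support
#' labels, and turn malformed input into an informative error.
#'
#' @param tree A `phylo` object.
#' @param path Output file; if `NULL`, the Newick string is returned.
#' @param digits Significant digits for branch lengths; default 10.
#' @return `write_newick()`: the Newick string (invisibly if written to a
#'   file). `read_newick()`: a `phylo` object.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text A Newick string (used when `path` is `NULL`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  src <- if (is.null(path)) "text input" else path
  tree <- tryCatch(
    if (is.null(path)) ape::read.tree(text = text) else ape::read.tree(path),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick in ", src)
  tree
}
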