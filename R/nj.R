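## Neighbor-joining tree construction (Saitou-Nei) with deterministic
## tie-breaking, and Newick serialization.

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: at each step join the pair minimizing
#' \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j} (row sums \eqn{R}), with branch
#' lengths \eqn{b_i = d_{ij}/2 + (R_i - R_j)/(2(r-2))} and the reduction
#' \eqn{d_{uk} = (d_{ik} + d_{jk} - d_{ij})/2}. Ties in Q are broken
#' deterministically towards the lexicographically first label pair. On
#' additive distances the tree's path lengths reproduce the input exactly.
#' Negative branch lengths are kept as estimated.
#'
#' @param d symmetric distance matrix with at least 3 labels.
#' @return an unrooted `"phylo"` tree (see \pkg{ape}) whose leaves are the
#'   matrix labels.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labs <- rownames(d)
  n <- length(labs)
  if (n < 3) stop("need at least 3 taxa")

  # phylo numbering: leaves 1..n, internals n+1 .. 2n-2
  node_id <- seq_len(n)            # ids of active nodes
  node_lab <- labs                 # labels used for tie-breaking
  next_internal <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  D <- d

  while (length(node_id) > 3L) {
    r <- length(node_id)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic label order decides ties
    key <- apply(cand, 1, function(ij) {
      p <- sort(node_lab[ij]); paste(p, collapse = "\r") })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    u <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, node_id[i]), c(u, node_id[j]))
    lens <- c(lens, bi, bj)
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
               c(duk[keep], 0))
    node_id <- c(node_id[keep], u)
    node_lab <- c(node_lab[keep], min(node_lab[c(i, j)]))
    dimnames(D) <- NULL
  }

  # final three nodes joined at one internal vertex (three-point formulas)
  u <- next_internal
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(edges, c(u, node_id[1]), c(u, node_id[2]), c(u, node_id[3]))
  lens <- c(lens, b1, b2, b3)

  # renumber internals so the top (degree-3) vertex is n+1, as ape expects
  remap <- function(v) ifelse(v <= n, v,
                              ifelse(v == u, n + 1L, as.integer(v + 1L)))
  edges <- cbind(remap(edges[, 1]), remap(edges[, 2]))
  storage.mode(edges) <- "integer"
  tr <- list(edge = edges, edge.length = unname(lens), tip.label = labs,
             Nnode = n - 2L)
  class(tr) <- "phylo"
  stats::reorder(tr, "cladewise")
}

#' Write a tree in Newick format
#'
#' Standard Newick text with branch lengths, via [ape::write.tree()].
#' Negative branch lengths are written as-is with a message.
#'
#' @param tree a `"phylo"` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (any(tree$edge.length < 0))
    message(sum(tree$edge.length < 0),
            " negative branch length(s) written as-is")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
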