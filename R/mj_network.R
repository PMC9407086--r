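## Weighted median-joining haplotype networks over single-copy STR loci,
## with mutation-rate-derived locus weights and ancestral-node inference.

# default locus set for lineage networks: 15 single-copy loci with
# DYS389II recoded as DYS389I + DYS389b (DYS389b = DYS389II - DYS389I)
.network_loci <- c("DYS19", "DYS389I", "DYS389b", "DYS390", "DYS391",
                   "DYS392", "DYS393", "DYS437", "DYS438", "DYS439",
                   "DYS448", "DYS456", "DYS458", "DYS635", "YGATAH4")

#' Default network locus set
#' @return character vector of 15 locus names (DYS389II enters as DYS389I
#'   plus the derived DYS389b).
#' @export
network_loci <- function() .network_loci

#' Collapse STR profiles to distinct network haplotypes
#'
#' Builds the integer repeat-value matrix over the network loci and merges
#' identical vectors, keeping per-population counts and member sample ids.
#' Samples with a null, duplicated or fractional (microvariant) allele at
#' any network locus are excluded with a message: the weighted Manhattan
#' step metric is undefined across fractional offsets.
#'
#' @param profiles a `"str_profiles"` object; run [derive_dys389b()] first
#'   when the loci include `DYS389b`.
#' @param loci loci spanning the haplotype vector (default
#'   [network_loci()]).
#' @return object of class `"net_haplotypes"`: list with `vectors` (m x L
#'   integer matrix), `counts` (m x populations), `members` (list of sample
#'   id vectors), `loci`, `populations`.
#' @export
net_haplotypes <- function(profiles, loci = network_loci()) {
  if ("DYS389b" %in% loci && !"DYS389b" %in% names(profiles))
    profiles <- derive_dys389b(profiles)
  missing_loci <- setdiff(loci, names(profiles))
  if (length(missing_loci))
    stop("profiles lack network loci: ", paste(missing_loci, collapse = ", "))
  n <- nrow(profiles)
  m <- matrix(NA_real_, n, length(loci), dimnames = list(NULL, loci))
  for (j in seq_along(loci)) {
    a <- profiles[[loci[j]]]
    ok <- lengths(a) == 1L
    m[ok, j] <- unlist(a[ok])
  }
  usable <- stats::complete.cases(m) &
    apply(m, 1, function(v) all(abs(v - round(v)) < 1e-9, na.rm = TRUE))
  if ("dys389b_flag" %in% names(profiles))
    usable <- usable & !profiles$dys389b_flag
  if (!all(usable))
    message(sum(!usable), " sample(s) excluded from the network stage ",
            "(null, duplicated or fractional calls): ",
            paste(utils::head(profiles$sample_id[!usable], 5), collapse = ", "),
            if (sum(!usable) > 5) ", ..." else "")
  m <- m[usable, , drop = FALSE]
  if (!nrow(m)) stop("no usable haplotypes for the network stage")
  storage.mode(m) <- "integer"
  key <- apply(m, 1, paste, collapse = "|")
  pops <- sort(unique(profiles$population[usable]))
  idx <- split(seq_len(nrow(m)), key)
  uniq <- matrix(unlist(lapply(idx, function(i) m[i[1], ])),
                 ncol = ncol(m), byrow = TRUE,
                 dimnames = list(NULL, colnames(m)))
  counts <- matrix(unlist(lapply(idx, function(i)
    as.integer(table(factor(profiles$population[usable][i],
                            levels = pops))))),
    ncol = length(pops), byrow = TRUE, dimnames = list(NULL, pops))
  structure(list(vectors = uniq, counts = counts,
                 members = lapply(idx, function(i)
                   profiles$sample_id[usable][i]),
                 loci = loci, populations = pops),
            class = "net_haplotypes")
}

#' @export
print.net_haplotypes <- function(x, ...) {
  cat(sprintf("%d distinct haplotypes over %d loci (%d samples, %d population(s))\n",
              nrow(x$vectors), ncol(x$vectors), sum(x$counts),
              length(x$populations)))
  invisible(x)
}

#' Locus weights from mutation rates
#'
#' Maps per-locus mutation rates to integer weights on the conventional 1-5
#' scale, the lower the rate the higher the weight: quintile bins of
#' log10(rate), lowest-rate quintile = 5, highest = 1. Equal rates get
#' equal weights (all-equal rates fall in the middle bin, weight 3).
#'
#' @param rates named numeric vector, locus -> per-generation mutation rate.
#' @param loci loci that must be covered (default: the names of `rates`).
#' @return data frame `locus, rate, weight` with the anti-monotone
#'   guarantee: a lower rate never gets a lower weight.
#' @export
weights_from_rates <- function(rates, loci = names(rates)) {
  if (!all(loci %in% names(rates)))
    stop("missing mutation rate for: ",
         paste(setdiff(loci, names(rates)), collapse = ", "))
  r <- rates[loci]
  if (any(!is.finite(r) | r <= 0)) stop("rates must be positive")
  lg <- log10(r)
  if (diff(range(lg)) < 1e-12) {
    w <- rep(3L, length(lg))
  } else {
    br <- stats::quantile(lg, probs = seq(0.2, 0.8, by = 0.2), names = FALSE)
    w <- 5L - findInterval(lg, br, left.open = TRUE)
  }
  data.frame(locus = loci, rate = unname(r), weight = as.integer(w),
             stringsAsFactors = FALSE)
}

# weighted Manhattan distance matrix between rows of integer matrices
wmanhattan <- function(A, B, w) {
  out <- matrix(0, nrow(A), nrow(B))
  for (l in seq_along(w))
    out <- out + w[l] * abs(outer(A[, l], B[, l], `-`))
  out
}

# Prim MST total cost on a dense symmetric distance matrix
mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- D[1, ]
  total <- 0
  for (step in seq_len(n - 1)) {
    i <- which(!intree)[which.min(mind[!intree])]
    total <- total + mind[i]
    intree[i] <- TRUE
    mind <- pmin(mind, D[i, ])
  }
  total
}

# epsilon-relaxed minimum spanning network: edge (u,v) kept iff
# d(u,v) <= single-linkage merge height(u,v) + eps
msn_edges <- function(D, eps = 0) {
  n <- nrow(D)
  if (n == 1) return(matrix(integer(0), 0, 2))
  sl <- stats::cophenetic(stats::hclust(stats::as.dist(D), method = "single"))
  sl <- as.matrix(sl)
  keep <- which(upper.tri(D) & D <= sl + eps + 1e-9, arr.ind = TRUE)
  keep
}

#' Build a weighted median-joining network
#'
#' Median-joining under the weighted Manhattan step metric: repeatedly
#' evaluate the component-wise median vectors of node triples and add the
#' one that most reduces the total spanning cost, until none helps; then
#' prune median vectors that no longer shorten any connection, and connect
#' the final node set by the epsilon-relaxed minimum spanning network.
#' Candidate medians are generated from all node triples, not only
#' network-adjacent ones — on small instances this reaches the same cost
#' as an exhaustive Steiner-point search over median candidates. With
#' `epsilon = 0` the edge set contains a minimum spanning tree under the
#' weighted metric.
#'
#' @param haps a `"net_haplotypes"` object (distinct vectors; duplicated
#'   observed vectors are an error — merge them with [net_haplotypes()]).
#' @param weights data frame from [weights_from_rates()] (or any with
#'   `locus` and `weight`), covering the haplotype loci. Default: all
#'   weights 1.
#' @param epsilon non-negative relaxation of the spanning-network
#'   threshold; 0 (default) gives the strict minimum spanning network.
#' @return object of class `"haplo_network"`: list with `graph` (an
#'   \pkg{igraph} graph; vertex attributes `name`, `is_median`, per-
#'   population counts; edge attribute `weight` = weighted step length),
#'   `vectors` (node vectors incl. medians), `counts`, `is_median`,
#'   `loci`, `weights`, `cost` (total spanning cost over the final node
#'   set).
#' @export
build_network <- function(haps, weights = NULL, epsilon = 0) {
  stopifnot(inherits(haps, "net_haplotypes"), epsilon >= 0)
  V <- haps$vectors
  if (nrow(V) < 2) stop("need at least 2 distinct haplotypes")
  if (anyDuplicated(apply(V, 1, paste, collapse = "|")))
    stop("duplicate observed vectors; merge them first")
  w <- resolve_weights(weights, haps$loci)

  is_median <- rep(FALSE, nrow(V))
  vec_key <- function(M) apply(M, 1, paste, collapse = "|")

  repeat {
    D <- wmanhattan(V, V, w)
    base_cost <- mst_cost(D)
    # candidate Steiner points: component-wise medians of all node triples
    # (observed and previously added medians alike)
    cand <- list()
    keys <- vec_key(V)
    for (u in seq_len(nrow(V) - 2)) for (v in seq(u + 1, nrow(V) - 1))
      for (x in seq(v + 1, nrow(V))) {
        med <- as.integer(apply(V[c(u, v, x), , drop = FALSE], 2,
                                function(a) sort(a)[2]))
        k <- paste(med, collapse = "|")
        if (k %in% keys) next
        cand[[k]] <- med
      }
    if (!length(cand)) break
    # keep the single candidate with the largest cost reduction
    gains <- vapply(cand, function(m) {
      Vm <- rbind(V, m)
      base_cost - mst_cost(wmanhattan(Vm, Vm, w))
    }, numeric(1))
    if (max(gains) <= 1e-9) break
    best <- names(cand)[order(-gains, names(cand))][1]
    V <- rbind(V, cand[[best]])
    is_median <- c(is_median, TRUE)
  }

  # prune medians whose removal leaves the spanning cost unchanged
  repeat {
    D <- wmanhattan(V, V, w)
    base_cost <- mst_cost(D)
    drop <- NA_integer_
    for (i in which(is_median)) {
      keep <- setdiff(seq_len(nrow(V)), i)
      if (mst_cost(D[keep, keep, drop = FALSE]) <= base_cost + 1e-9) {
        drop <- i; break
      }
    }
    if (is.na(drop)) break
    V <- V[-drop, , drop = FALSE]
    is_median <- is_median[-drop]
  }

  D <- wmanhattan(V, V, w)
  E <- msn_edges(D, epsilon)
  counts <- matrix(0L, nrow(V), ncol(haps$counts),
                   dimnames = list(NULL, colnames(haps$counts)))
  okey <- vec_key(haps$vectors)
  match_obs <- match(vec_key(V), okey)
  counts[!is.na(match_obs), ] <- haps$counts[match_obs[!is.na(match_obs)], ,
                                             drop = FALSE]
  ids <- ifelse(is_median, paste0("mv", cumsum(is_median)),
                paste0("H", seq_len(nrow(V)) - cumsum(is_median)))
  g <- igraph::make_empty_graph(n = nrow(V), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "is_median", value = is_median)
  for (p in colnames(counts))
    g <- igraph::set_vertex_attr(g, p, value = counts[, p])
  if (nrow(E))
    g <- igraph::add_edges(g, t(E), weight = D[E])
  structure(list(graph = g, vectors = V, counts = counts,
                 is_median = is_median, loci = haps$loci,
                 weights = w, cost = mst_cost(D), node_ids = ids),
            class = "haplo_network")
}

resolve_weights <- function(weights, loci) {
  if (is.null(weights)) return(stats::setNames(rep(1, length(loci)), loci))
  if (is.data.frame(weights))
    weights <- stats::setNames(weights$weight, weights$locus)
  if (!all(loci %in% names(weights)))
    stop("missing weight for: ", paste(setdiff(loci, names(weights)),
                                       collapse = ", "))
  weights[loci]
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("Median-joining network: %d nodes (%d median), %d edges, cost %.1f\n",
              nrow(x$vectors), sum(x$is_median),
              igraph::ecount(x$graph), x$cost))
  invisible(x)
}

#' Infer the ancestral haplotype
#'
#' Picks the observed haplotype with the smallest total weighted distance
#' to all sampled chromosomes, \eqn{\sum_j c_j\, d_w(h, h_j)} with counts
#' \eqn{c_j} — the weighted medoid. Ties go to the haplotype with the
#' larger own count, then to lexicographic vector order.
#'
#' @param haps a `"net_haplotypes"` object.
#' @param weights locus weights as in [build_network()].
#' @return list with `index` (row in `haps$vectors`), `vector` and `score`.
#' @export
ancestral_node <- function(haps, weights = NULL) {
  stopifnot(inherits(haps, "net_haplotypes"))
  w <- resolve_weights(weights, haps$loci)
  V <- haps$vectors
  cnt <- rowSums(haps$counts)
  D <- wmanhattan(V, V, w)
  score <- as.numeric(D %*% cnt)
  best <- which(score <= min(score) + 1e-9)
  if (length(best) > 1) {
    best <- best[cnt[best] == max(cnt[best])]
    if (length(best) > 1) {
      keys <- apply(V[best, , drop = FALSE], 1, function(v)
        paste(sprintf("%06d", v), collapse = ""))
      best <- best[order(keys)]
    }
  }
  i <- best[1]
  list(index = unname(i), vector = V[i, ], score = unname(score[i]))
}

#' Population composition relative to the ancestral haplotype
#'
#' For each population: number of distinct haplotypes, number of sampled
#' chromosomes, and the count-weighted mean and median weighted distance of
#' its haplotypes to the ancestral node. A larger mean distance marks a
#' population lying "downstream" of the ancestral type.
#'
#' @param haps a `"net_haplotypes"` object.
#' @param weights locus weights as in [build_network()].
#' @param ancestor optional result of [ancestral_node()]; computed if
#'   missing.
#' @return data frame `population, n_haplotypes, n_samples,
#'   mean_dist_to_ancestor, median_dist_to_ancestor`.
#' @export
network_composition_summary <- function(haps, weights = NULL,
                                        ancestor = NULL) {
  w <- resolve_weights(weights, haps$loci)
  if (is.null(ancestor)) ancestor <- ancestral_node(haps, weights)
  d <- as.numeric(wmanhattan(haps$vectors,
                             matrix(ancestor$vector, 1), w))
  out <- list()
  for (p in haps$populations) {
    cnt <- haps$counts[, p]
    if (sum(cnt) == 0) {
      message("population '", p, "' has no haplotypes in the network")
      next
    }
    reps <- rep(d, cnt)
    out[[p]] <- data.frame(population = p,
                           n_haplotypes = sum(cnt > 0),
                           n_samples = sum(cnt),
                           mean_dist_to_ancestor = mean(reps),
                           median_dist_to_ancestor = stats::median(reps),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Export network node and edge tables
#'
#' @param net a `"haplo_network"`.
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv` and
#'   `<prefix>_edges.tsv`.
#' @return the two paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  nodes <- data.frame(id = net$node_ids,
                      is_median = net$is_median,
                      vector = apply(net$vectors, 1, paste, collapse = "-"),
                      net$counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
  ends <- igraph::as_edgelist(net$graph, names = FALSE)
  edges <- data.frame(
    u = net$node_ids[ends[, 1]], v = net$node_ids[ends[, 2]],
    length = igraph::edge_attr(net$graph, "weight"),
    steps = apply(ends, 1, function(e)
      paste(abs(net$vectors[e[1], ] - net$vectors[e[2], ]), collapse = "-")),
    stringsAsFactors = FALSE)
  np <- paste0(prefix, "_nodes.tsv"); ep <- paste0(prefix, "_edges.tsv")
  utils::write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(np, ep))
}
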